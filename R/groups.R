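#' Canonical Hox/ParaHox group label for a common name
#'
#' Maps (case-insensitively) a protein's common name to a canonical label.
#' Deuterostome names follow the vertebrate nomenclature (mouse as standard):
#' `Hox1`..`Hox13` / `PG1`..`PG13` map to paralog groups PG1-PG13.
#' Protostome names map through a synonym table: `Lab`->PG1, `Pb`->PG2,
#' `Dfd`->PG4, `Scr`->PG5, `Antp`->PG7, `Ubx`/`Abd-A`->central,
#' `Abd-B`->posterior. ParaHox synonyms: `Xlox`/`IPF1`->Pdx, `ind`/`Gsh`->Gsx,
#' `cad`/`caudal`->Cdx. Range aliases `anterior` (PG1-2), `central` (PG4-8)
#' and `posterior` (PG9-13) are accepted as names. Every name maps to exactly
#' one canonical label; unknown names map to category OTHER, never silently
#' to a Hox group.
#'
#' @param name common name string (e.g. `"Hox3"`, `"Xlox"`, `"Abd-B"`).
#' @return list with elements `category` (one of `"HOX"`, `"PARAHOX"`,
#'   `"OTHER"`) and `name` (canonical group name, or `"OTHER"`).
#' @export
canonical_group <- function(name) {
  key <- tolower(trimws(name))
  key <- gsub("[ _]", "-", key)
  hox <- function(g) list(category = "HOX", name = g)
  parahox <- function(g) list(category = "PARAHOX", name = g)
  other <- list(category = "OTHER", name = "OTHER")
  if (!nzchar(key)) return(other)

  if (grepl("^(hox|pg)-?[0-9]{1,2}[a-z]?$", key)) {
    n <- as.integer(gsub("[^0-9]", "", key))
    if (n >= 1 && n <= 13) return(hox(paste0("PG", n)))
    return(other)
  }

  synonyms <- c(lab = "PG1", pb = "PG2", zen = "PG3", dfd = "PG4",
                scr = "PG5", antp = "PG7",
                ubx = "central", `abd-a` = "central", abda = "central",
                `abd-b` = "posterior", abdb = "posterior",
                anterior = "anterior", central = "central",
                posterior = "posterior")
  if (key %in% names(synonyms)) return(hox(unname(synonyms[key])))

  if (grepl("^(gsx|gsh|ind$)", key)) return(parahox("Gsx"))
  if (grepl("^(pdx|xlox|ipf1)", key)) return(parahox("Pdx"))
  if (grepl("^(cdx|cad$|caudal$)", key)) return(parahox("Cdx"))

  other
}

#' Collapse specific Hox paralog groups into the paper-style classes
#'
#' PG1, PG2 and PG3 stay as themselves, PG4-PG8 collapse to `central` and
#' PG9-PG13 to `posterior` (the operational definitions used throughout:
#' central = PG4-8, posterior = PG9-13). Range aliases pass through;
#' anything else is returned unchanged.
#'
#' @param group_name character vector of canonical group names.
#' @return character vector of collapsed class names.
#' @export
collapse_hox_class <- function(group_name) {
  vapply(group_name, function(g) {
    m <- regmatches(g, regexec("^PG([0-9]{1,2})$", g))[[1]]
    if (length(m) == 2) {
      n <- as.integer(m[2])
      if (n >= 4 && n <= 8) return("central")
      if (n >= 9) return("posterior")
      return(g)
    }
    g
  }, character(1), USE.NAMES = FALSE)
}
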