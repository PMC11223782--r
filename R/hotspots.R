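#' Parse a per-residue free-energy-change table
#'
#' Two dialects are supported. `"tsv"` expects columns `chain`, `resnum`,
#' `resname`, `ddg` (kcal/mol), tab- or comma-separated with a header.
#' `"foldx_ala_scan"` expects the per-residue text lines of an alanine-scan
#' output, e.g. `THR A 18 to ALA energy change is 0.52`.
#'
#' @param path Table file path.
#' @param dialect `"tsv"` or `"foldx_ala_scan"`.
#' @return Data frame of `hotspot_record`s: `chain`, `resnum`, `insert`,
#'   `resname`, `ddg`, with `label` unset (`NA`).
#' @export
parse_ddg_table <- function(path, dialect = c("tsv", "foldx_ala_scan")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (dialect == "tsv") {
    sep <- if (grepl("\t", lines[1])) "\t" else ","
    tab <- utils::read.table(text = lines, header = TRUE, sep = sep,
                             stringsAsFactors = FALSE,
                             colClasses = "character")
    need <- c("chain", "resnum", "resname", "ddg")
    if (!all(need %in% names(tab))) {
      stop("tsv ddg table must have columns: ",
           paste(need, collapse = ", "), call. = FALSE)
    }
    ddg <- suppressWarnings(as.numeric(tab$ddg))
    if (anyNA(ddg)) {
      bad <- which(is.na(ddg))[1]
      stop("malformed ddg value at line ", bad + 1L, ": '",
           tab$ddg[bad], "'", call. = FALSE)
    }
    out <- data.frame(chain = tab$chain,
                      resnum = as.integer(tab$resnum),
                      insert = "",
                      resname = tab$resname,
                      ddg = ddg, stringsAsFactors = FALSE)
  } else {
    pat <- "^\\s*([A-Z]{3})\\s+(\\S+)\\s+(-?[0-9]+)([A-Za-z]?)\\s+to\\s+\\S+\\s+energy\\s+change\\s+is\\s+(-?[0-9.eE+]+)\\s*$"
    m <- regmatches(lines, regexec(pat, lines))
    bad <- which(vapply(m, length, integer(1)) == 0L)
    if (length(bad)) {
      stop("malformed alanine-scan line ", bad[1], ": '", lines[bad[1]], "'",
           call. = FALSE)
    }
    out <- data.frame(
      chain = vapply(m, `[`, character(1), 3),
      resnum = as.integer(vapply(m, `[`, character(1), 4)),
      insert = vapply(m, `[`, character(1), 5),
      resname = vapply(m, `[`, character(1), 2),
      ddg = as.numeric(vapply(m, `[`, character(1), 6)),
      stringsAsFactors = FALSE
    )
  }
  out$label <- NA_character_
  out
}

#' Hot-spot label from a free-energy change
#'
#' `CRITICAL` when the destabilization is `critical_min` kcal/mol or more,
#' `WARM` in `[warm_min, critical_min)`, `NONE` below `warm_min` (including
#' stabilizing, negative changes).
#'
#' @param ddg Free-energy change(s), kcal/mol.
#' @param critical_min Critical hot-spot threshold (default 1.5).
#' @param warm_min Warm hot-spot threshold (default 0.5); must be below
#'   `critical_min`.
#' @return Character vector of labels.
#' @export
classify_hotspot <- function(ddg, critical_min = 1.5, warm_min = 0.5) {
  stopifnot(warm_min < critical_min)
  ifelse(ddg >= critical_min, "CRITICAL",
         ifelse(ddg >= warm_min, "WARM", "NONE"))
}

#' Label every record of a ddG table
#'
#' @param records Data frame from [parse_ddg_table()].
#' @inheritParams classify_hotspot
#' @return The records with the `label` column filled.
#' @export
label_hotspots <- function(records, critical_min = 1.5, warm_min = 0.5) {
  records$label <- classify_hotspot(records$ddg, critical_min, warm_min)
  records
}
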