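#' Parse experimental quality metadata from a structure header
#'
#' Reads the experimental method, resolution, R-work/R-free and (for cryo-EM)
#' Fourier shell correlation from a PDB header (EXPDTA, REMARK 2, REMARK 3)
#' or from mmCIF `_exptl`, `_refine` and `_em_3d_reconstruction` categories.
#' Absent numeric fields are `NA`, never 0.
#'
#' @param path Structure file path.
#' @param format `"auto"`, `"pdb"` or `"mmcif"`.
#' @return A `quality_record`: list with `structure_id`, `method` (one of
#'   `"XRAY"`, `"CRYOEM"`, `"NMR"`, `"OTHER"`), `resolution`, `r_free`,
#'   `r_factor`, `fsc`.
#' @export
parse_quality <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif" else "pdb"
  }
  lines <- readLines(path, warn = FALSE)
  if (format == "pdb") {
    q <- parse_quality_pdb(lines)
  } else {
    q <- parse_quality_cif(lines)
  }
  if (is.na(q$method)) {
    stop("metadata error: no experimental method record in '", path, "'",
         call. = FALSE)
  }
  q$structure_id <- tools::file_path_sans_ext(basename(path))
  if (!is.na(q$resolution) && q$resolution <= 0) {
    stop("metadata error: non-positive resolution", call. = FALSE)
  }
  class(q) <- "quality_record"
  q
}

method_from_text <- function(txt) {
  txt <- toupper(txt)
  if (grepl("NMR", txt)) return("NMR")
  if (grepl("ELECTRON MICROSCOPY|CRYO", txt)) return("CRYOEM")
  if (grepl("X-RAY|XRAY", txt)) return("XRAY")
  "OTHER"
}

num_from <- function(lines, pattern) {
  hit <- grep(pattern, lines, value = TRUE)
  if (!length(hit)) return(NA_real_)
  rest <- sub(pattern, "", hit[1])
  m <- regmatches(rest, regexpr("[0-9]*\\.?[0-9]+", rest))
  if (!length(m)) return(NA_real_)
  as.numeric(m)
}

parse_quality_pdb <- function(lines) {
  head <- lines[!grepl("^(ATOM|HETATM)", lines)]
  expdta <- grep("^EXPDTA", head, value = TRUE)
  method <- if (length(expdta)) method_from_text(expdta[1]) else NA_character_
  res <- num_from(head, "^REMARK   2 RESOLUTION\\.")
  # REMARK 3: take the working-set R value and the plain FREE R VALUE line
  # (skipping error-estimate and test-set variants)
  r3 <- head[grepl("^REMARK   3", head)]
  r_factor <- num_from(r3, ".*R VALUE\\s+\\(WORKING SET\\)\\s*:")
  free_lines <- r3[grepl("FREE R VALUE\\s*:", r3) &
                     !grepl("ESU|ERROR|TEST|COUNT", r3)]
  r_free <- num_from(free_lines, ".*FREE R VALUE\\s*:")
  fsc <- num_from(r3, ".*FOURIER SHELL CORRELATION\\s*:")
  if (is.na(fsc)) fsc <- num_from(r3, ".*\\bFSC\\b\\s*:")
  list(method = method, resolution = res, r_free = r_free,
       r_factor = r_factor, fsc = fsc)
}

cif_value <- function(lines, key) {
  hit <- grep(paste0("^", key, "\\s"), lines, value = TRUE)
  if (!length(hit)) return(NA_character_)
  v <- trimws(sub(paste0("^", key, "\\s+"), "", hit[1]))
  gsub("^['\"]|['\"]$", "", v)
}

parse_quality_cif <- function(lines) {
  m <- cif_value(lines, "_exptl\\.method")
  method <- if (is.na(m)) NA_character_ else method_from_text(m)
  as_num <- function(v) {
    if (is.na(v) || v %in% c(".", "?")) NA_real_ else suppressWarnings(as.numeric(v))
  }
  res <- as_num(cif_value(lines, "_refine\\.ls_d_res_high"))
  if (is.na(res)) {
    res <- as_num(cif_value(lines, "_em_3d_reconstruction\\.resolution"))
  }
  list(
    method = method,
    resolution = res,
    r_free = as_num(cif_value(lines, "_refine\\.ls_R_factor_R_free")),
    r_factor = as_num(cif_value(lines, "_refine\\.ls_R_factor_R_work")),
    fsc = as_num(cif_value(lines, "_em_3d_reconstruction\\.fsc_threshold"))
  )
}

#' Construct a quality record directly
#'
#' @param structure_id Identifier.
#' @param method `"XRAY"`, `"CRYOEM"`, `"NMR"` or `"OTHER"`.
#' @param resolution,r_free,r_factor,fsc Numeric metrics; `NA` when absent.
#' @return A `quality_record`.
#' @export
quality_record <- function(structure_id, method, resolution = NA_real_,
                           r_free = NA_real_, r_factor = NA_real_,
                           fsc = NA_real_) {
  stopifnot(method %in% c("XRAY", "CRYOEM", "NMR", "OTHER"))
  q <- list(structure_id = structure_id, method = method,
            resolution = resolution, r_free = r_free,
            r_factor = r_factor, fsc = fsc)
  class(q) <- "quality_record"
  q
}

#' Structure quality filter
#'
#' NMR structures pass the metric checks unconditionally. X-ray structures
#' pass when resolution <= `resolution_xray_max` and
#' (R-free - R-factor) <= `rgap_max`. Cryo-EM structures pass when
#' resolution <= `resolution_cryoem_max` and FSC <= `fsc_max`. Any other
#' method fails, and a missing required metric fails closed.
#'
#' @param q A `quality_record`.
#' @param config Quality thresholds, see [default_config()] element `quality`.
#' @return List with `pass` (logical) and `reason` (character).
#' @export
passes_quality <- function(q, config = default_config()$quality) {
  if (q$method == "NMR") {
    return(list(pass = TRUE, reason = "nmr"))
  }
  if (q$method == "XRAY") {
    if (is.na(q$resolution) || is.na(q$r_free) || is.na(q$r_factor)) {
      return(list(pass = FALSE, reason = "missing metric"))
    }
    if (q$resolution > config$resolution_xray_max) {
      return(list(pass = FALSE, reason = "resolution"))
    }
    if (q$r_free - q$r_factor > config$rgap_max) {
      return(list(pass = FALSE, reason = "r-free gap"))
    }
    return(list(pass = TRUE, reason = ""))
  }
  if (q$method == "CRYOEM") {
    if (is.na(q$resolution) || is.na(q$fsc)) {
      return(list(pass = FALSE, reason = "missing metric"))
    }
    if (q$resolution > config$resolution_cryoem_max) {
      return(list(pass = FALSE, reason = "resolution"))
    }
    if (q$fsc > config$fsc_max) {
      return(list(pass = FALSE, reason = "fsc"))
    }
    return(list(pass = TRUE, reason = ""))
  }
  list(pass = FALSE, reason = "method not allowed")
}
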