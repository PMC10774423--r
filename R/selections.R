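#' Load named residue selections from a structured text file
#'
#' The fixture format is tab-separated with columns `name` and `residues`;
#' the residue field is a comma-separated list of ids and `from-to` ranges.
#' All ids are validated against the BIR2 domain range 163-234.
#'
#' @param path Selections file; default: the packaged BIR2 fixture (domain,
#'   helices 163-168 and 181-186, RIP2-binding loops 174-182 and 205-215,
#'   the 192-198 region, beta segments 198-200 and 206-208, the 201-204
#'   turn, the 11-residue hydrophobic core, and the CCHC Zn-finger quartet).
#' @param name Optional single selection to return as an integer vector;
#'   unknown names error with the list of available names.
#' @return Named list of sorted unique integer vectors, or one vector if
#'   `name` is given.
#' @examples
#' length(load_selections(name = "hydrophobic_core"))  # 11
#' @export
load_selections <- function(path = NULL, name = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "bir2_selections.tsv", package = "bir2dyn")
  }
  if (!file.exists(path)) abort(paste("selections file not found:", path))
  df <- utils::read.delim(path, comment.char = "#", sep = "\t",
                          stringsAsFactors = FALSE)
  stopifnot(all(c("name", "residues") %in% names(df)))
  sel <- lapply(df$residues, function(spec) {
    parts <- strsplit(spec, ",")[[1]]
    ids <- unlist(lapply(parts, function(p) {
      if (grepl("-", p)) {
        ab <- as.integer(strsplit(p, "-")[[1]])
        seq.int(ab[1], ab[2])
      } else {
        as.integer(p)
      }
    }))
    sort(unique(ids))
  })
  names(sel) <- df$name
  bad <- vapply(sel, function(s) any(s < 163 | s > 234), logical(1))
  if (any(bad)) {
    abort(paste("selection(s) outside the 163-234 domain range:",
                paste(names(sel)[bad], collapse = ", ")))
  }
  if (vapply(sel, length, integer(1)) |> min() == 0) {
    abort("empty selection in file")
  }
  if (!is.null(name)) {
    if (!name %in% names(sel)) {
      abort(paste0("unknown selection '", name, "'; available: ",
                   paste(names(sel), collapse = ", ")))
    }
    return(sel[[name]])
  }
  sel
}
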