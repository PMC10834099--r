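#' Construct a coefficient table
#'
#' Each biomarker carries an effect-direction coefficient: `+1` when the
#' biologically meaningful response is induction (the biomarker increases
#' under stress), `-1` when it is inhibition. The coefficient flips the
#' standardized score in the IBR pathway so adverse responses always point
#' outward on the star plot.
#'
#' @param biomarker Character vector of biomarker names.
#' @param coefficient Vector of `+1`/`-1` values, one per biomarker.
#' @return A data.frame of class `coefficient_table`.
#' @export
coefficient_table <- function(biomarker, coefficient) {
  biomarker <- as.character(biomarker)
  if (length(biomarker) != length(coefficient)) {
    stop("`biomarker` and `coefficient` lengths differ", call. = FALSE)
  }
  if (anyDuplicated(biomarker)) {
    stop("duplicate biomarker rows: ",
         paste(unique(biomarker[duplicated(biomarker)]), collapse = ", "),
         call. = FALSE)
  }
  coefficient <- suppressWarnings(as.numeric(coefficient))
  if (any(is.na(coefficient)) || !all(coefficient %in% c(-1, 1))) {
    stop("coefficients must be exactly +1 or -1", call. = FALSE)
  }
  structure(data.frame(biomarker = biomarker,
                       coefficient = as.integer(coefficient),
                       stringsAsFactors = FALSE),
            class = c("coefficient_table", "data.frame"))
}

#' Read a coefficient table from a delimited file
#'
#' Expects a two-column table (biomarker name, coefficient) with a header
#' row. Coefficients must be exactly `+1` or `-1`.
#'
#' @inheritParams read_biomarker_table
#' @return A [coefficient_table()].
#' @export
read_coefficient_table <- function(path, delimiter = NULL) {
  raw <- read_delim_chr(path, delimiter)
  if (ncol(raw) != 2L) {
    stop("'", path, "': a coefficient table has exactly two columns ",
         "(biomarker, coefficient); got ", ncol(raw), call. = FALSE)
  }
  coefficient_table(raw[[1L]], raw[[2L]])
}

#' Default coefficients for a biomarker table
#'
#' When no coefficient table is provided the analysis runs with the value 1
#' for every biomarker, i.e. every biomarker is treated as induced.
#'
#' @param x A [biomarker_table()].
#' @return A [coefficient_table()] with coefficient `+1` for every
#'   biomarker, in table order.
#' @export
default_coefficients <- function(x) {
  x <- biomarker_table(x)
  bmk <- biomarker_names(x)
  if (length(bmk) == 0L) stop("table has no biomarker columns", call. = FALSE)
  coefficient_table(bmk, rep(1L, length(bmk)))
}

# coefficient vector aligned to `biomarkers`, defaulting to all +1
align_coefficients <- function(coef, biomarkers) {
  if (is.null(coef)) {
    return(stats::setNames(rep(1, length(biomarkers)), biomarkers))
  }
  if (!inherits(coef, "coefficient_table")) {
    coef <- coefficient_table(coef[[1L]], coef[[2L]])
  }
  missing <- setdiff(biomarkers, coef$biomarker)
  if (length(missing) > 0L) {
    stop("no coefficient for biomarker(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  stats::setNames(coef$coefficient[match(biomarkers, coef$biomarker)],
                  biomarkers)
}
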