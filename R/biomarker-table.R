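#' Construct a biomarker table
#'
#' A biomarker table holds raw per-sample measurements: a site (station /
#' treatment) label per row and one numeric column per biomarker. Replicate
#' rows per site are allowed, and missing measurements are represented as
#' `NA`. This is the common input of both the IBR and the IBRv2 workflow.
#'
#' @param x A data.frame whose first column contains site labels and whose
#'   remaining columns are numeric biomarker measurements.
#' @return An object of class `biomarker_table` (a data.frame).
#' @seealso [read_biomarker_table()], [validate_biomarkers()],
#'   [aggregate_site_means()]
#' @export
biomarker_table <- function(x) {
  if (!is.data.frame(x)) stop("`x` must be a data.frame", call. = FALSE)
  if (ncol(x) < 2L) {
    stop("a biomarker table needs a site column plus at least one biomarker column",
         call. = FALSE)
  }
  bmk <- names(x)[-1L]
  if (anyDuplicated(bmk)) {
    stop("duplicate biomarker column names: ",
         paste(unique(bmk[duplicated(bmk)]), collapse = ", "), call. = FALSE)
  }
  for (nm in bmk) {
    if (!is.numeric(x[[nm]])) {
      stop("biomarker column '", nm, "' is not numeric", call. = FALSE)
    }
  }
  x[[1L]] <- as.character(x[[1L]])
  structure(as.data.frame(x, stringsAsFactors = FALSE),
            class = c("biomarker_table", "data.frame"))
}

#' @export
print.biomarker_table <- function(x, ...) {
  cat("<biomarker_table> ", length(site_levels(x)), " sites, ",
      ncol(x) - 1L, " biomarkers, ", nrow(x), " samples\n", sep = "")
  print(as.data.frame(x), ...)
  invisible(x)
}

#' Biomarker names of a table
#' @param x A `biomarker_table`.
#' @return Character vector of biomarker column names, in input order.
#' @export
biomarker_names <- function(x) names(x)[-1L]

# site labels in first-appearance order (all outputs preserve this order)
site_levels <- function(x) unique(as.character(x[[1L]]))

# tokens treated as missing in delimited input (case-insensitive)
.na_tokens <- c("", "na", "nan")

#' Read a biomarker table from a delimited file
#'
#' Reads a CSV/TSV file with a header row whose first column is the site
#' label and whose remaining columns are numeric biomarker measurements.
#' The delimiter is auto-detected from the file extension (`.tsv`/`.txt`
#' use a tab, everything else a comma) and can be overridden. The tokens
#' `""`, `"NA"` and `"NaN"` (case-insensitive) are read as missing values;
#' any other non-numeric cell in a biomarker column is an error.
#'
#' @param path Path to the delimited file.
#' @param delimiter Field delimiter; `NULL` (default) auto-detects from the
#'   file extension.
#' @return A [biomarker_table()].
#' @export
read_biomarker_table <- function(path, delimiter = NULL) {
  raw <- read_delim_chr(path, delimiter)
  if (ncol(raw) < 2L) {
    stop("'", path, "': expected a site column plus biomarker columns", call. = FALSE)
  }
  for (j in seq_len(ncol(raw))[-1L]) {
    col <- raw[[j]]
    miss <- is.na(col) | tolower(trimws(col)) %in% .na_tokens
    num <- suppressWarnings(as.numeric(col))
    bad <- !miss & is.na(num)
    if (any(bad)) {
      stop("'", path, "': non-numeric value \"", col[which(bad)[1L]],
           "\" in biomarker column '", names(raw)[j], "' (row ",
           which(bad)[1L], ")", call. = FALSE)
    }
    num[miss] <- NA_real_
    raw[[j]] <- num
  }
  biomarker_table(raw)
}

# shared character-mode delimited reader; keeps every cell as text so the
# caller can distinguish missing-value tokens from genuine parse failures
read_delim_chr <- function(path, delimiter = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(delimiter)) {
    ext <- tolower(tools::file_ext(path))
    delimiter <- if (ext %in% c("tsv", "txt", "tab")) "\t" else ","
  }
  utils::read.table(path, header = TRUE, sep = delimiter, quote = "\"",
                    colClasses = "character", check.names = FALSE,
                    na.strings = character(), stringsAsFactors = FALSE,
                    strip.white = TRUE, comment.char = "")
}

#' Write a biomarker table to a delimited file
#'
#' Values are written with 17 significant digits so that a write/read
#' round trip reproduces every finite measurement bit-identically and
#' preserves missingness.
#'
#' @param x A [biomarker_table()].
#' @param path Output path; the extension selects the delimiter as in
#'   [read_biomarker_table()].
#' @param delimiter Optional delimiter override.
#' @return `path`, invisibly.
#' @export
write_biomarker_table <- function(x, path, delimiter = NULL) {
  x <- biomarker_table(x)
  if (is.null(delimiter)) {
    ext <- tolower(tools::file_ext(path))
    delimiter <- if (ext %in% c("tsv", "txt", "tab")) "\t" else ","
  }
  out <- as.data.frame(x, stringsAsFactors = FALSE)
  for (j in seq_len(ncol(out))[-1L]) {
    v <- out[[j]]
    out[[j]] <- ifelse(is.na(v), "NA", sprintf("%.17g", v))
  }
  utils::write.table(out, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Validate a biomarker table
#'
#' Checks the admissibility rules for multibiomarker index input: between
#' three and nine biomarker columns, at least three non-missing values per
#' biomarker, at least two distinct sites, and no site/biomarker cell whose
#' replicates are all missing. The result is a report; nothing is thrown.
#'
#' @param x A [biomarker_table()].
#' @return A `validation_report`: list with `ok` (logical) and `violations`
#'   (data.frame with columns `rule` and `message`).
#' @export
validate_biomarkers <- function(x) {
  x <- biomarker_table(x)
  rules <- character()
  msgs <- character()
  k <- ncol(x) - 1L
  if (k < 3L || k > 9L) {
    rules <- c(rules, "biomarker_count")
    msgs <- c(msgs, sprintf(
      "three to nine biomarkers are required; got %d", k))
  }
  for (nm in biomarker_names(x)) {
    n_obs <- sum(!is.na(x[[nm]]))
    if (n_obs < 3L) {
      rules <- c(rules, "min_non_na")
      msgs <- c(msgs, sprintf(
        "biomarker '%s' has %d values other than NA; at least three are required",
        nm, n_obs))
    }
  }
  sites <- site_levels(x)
  if (length(sites) < 2L) {
    rules <- c(rules, "site_count")
    msgs <- c(msgs, sprintf("at least two distinct sites are required; got %d",
                            length(sites)))
  }
  for (s in sites) {
    rows <- x[[1L]] == s
    for (nm in biomarker_names(x)) {
      if (all(is.na(x[[nm]][rows]))) {
        rules <- c(rules, "all_missing_cell")
        msgs <- c(msgs, sprintf(
          "site '%s' has no non-missing value for biomarker '%s'", s, nm))
      }
    }
  }
  report <- list(ok = length(rules) == 0L,
                 violations = data.frame(rule = rules, message = msgs,
                                         stringsAsFactors = FALSE))
  class(report) <- "validation_report"
  report
}

#' @export
print.validation_report <- function(x, ...) {
  if (x$ok) {
    cat("<validation_report> ok\n")
  } else {
    cat("<validation_report>", nrow(x$violations), "violation(s):\n")
    for (m in x$violations$message) cat(" -", m, "\n")
  }
  invisible(x)
}

# stop on validation failure; `force` waives only the 3-9 count rule,
# never the >=3 non-NA rule
assert_valid <- function(x, force = FALSE) {
  rep <- validate_biomarkers(x)
  viol <- rep$violations
  if (force) viol <- viol[viol$rule != "biomarker_count", , drop = FALSE]
  if (nrow(viol) > 0L) {
    stop("invalid biomarker table:\n  ",
         paste(viol$message, collapse = "\n  "), call. = FALSE)
  }
  invisible(x)
}

#' Aggregate replicate rows to per-site means
#'
#' Both indexes operate on site-level values, so replicate measurements are
#' first averaged per site and biomarker (arithmetic mean over the
#' non-missing replicates). Site order is first appearance in the input.
#'
#' @param x A [biomarker_table()].
#' @return A numeric matrix (sites x biomarkers) of class `site_mean_matrix`
#'   with site labels as row names.
#' @export
aggregate_site_means <- function(x) {
  x <- biomarker_table(x)
  sites <- site_levels(x)
  bmk <- biomarker_names(x)
  m <- matrix(NA_real_, nrow = length(sites), ncol = length(bmk),
              dimnames = list(sites, bmk))
  for (s in sites) {
    rows <- x[[1L]] == s
    for (nm in bmk) {
      v <- x[[nm]][rows]
      v <- v[!is.na(v)]
      if (length(v) == 0L) {
        stop("site '", s, "' has no non-missing value for biomarker '", nm, "'",
             call. = FALSE)
      }
      m[s, nm] <- mean(v)
    }
  }
  class(m) <- c("site_mean_matrix", class(m))
  m
}

# accept either a raw biomarker table (data.frame) or a site-mean matrix;
# used by ibr_std() and ibrv2_bdi() so both mirror the one-call workflow
as_site_means <- function(x, force = FALSE) {
  if (inherits(x, "site_mean_matrix")) return(x)
  if (is.matrix(x)) {
    if (is.null(rownames(x)) || is.null(colnames(x))) {
      stop("a site-mean matrix needs site row names and biomarker column names",
           call. = FALSE)
    }
    class(x) <- c("site_mean_matrix", class(x))
    return(x)
  }
  x <- biomarker_table(x)
  assert_valid(x, force = force)
  aggregate_site_means(x)
}
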