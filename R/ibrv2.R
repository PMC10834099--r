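#' Biomarker deviation index (A parameters) relative to a reference site
#'
#' First step of the Integrated Biological Responses version 2 (IBRv2)
#' calculation. Per biomarker j, each site's mean is expressed as a natural
#' log-ratio to the reference site, Y_ij = log(m_ij / m_0j); the Y are
#' standardized over all sites including the reference (mean mu_j, sample
#' SD sigma_j): Z_ij = (Y_ij - mu_j) / sigma_j; and the biomarker deviation
#' index is the difference to the reference, A_ij = Z_ij - Z_0j. Positive A
#' indicates upregulation relative to the reference, negative A
#' downregulation. A biomarker identical across all sites (sigma_j = 0) has
#' zero deviation everywhere and gets Z = A = 0.
#'
#' @param x A [biomarker_table()] of raw replicate measurements, or a
#'   site-mean matrix as returned by [aggregate_site_means()]. All site
#'   means must be strictly positive (the log-ratio must be defined).
#' @param reference Reference site label; default is the first site in
#'   input order.
#' @param force Waive the 3-9 biomarker-count rule during validation.
#' @return An object of class `ibrv2_bdi`: list with `sites` (reference
#'   first), `biomarkers`, `reference`, and the sites x biomarkers matrices
#'   `Y`, `Z`, `A`.
#' @examples
#' tab <- data.frame(site = rep(c("ref", "s1", "s2"), each = 2),
#'                   cat = c(10, 12, 20, 24, 8, 9),
#'                   gst = c(50, 52, 70, 74, 40, 42),
#'                   ache = c(5, 6, 3, 4, 7, 8))
#' ibrv2_bdi(biomarker_table(tab))$A
#' @export
ibrv2_bdi <- function(x, reference = NULL, force = FALSE) {
  m <- as_site_means(x, force = force)
  sites <- rownames(m)
  if (is.null(reference)) reference <- sites[1L]
  if (!reference %in% sites) {
    stop("unknown reference site '", reference, "'", call. = FALSE)
  }
  bad <- which(m <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop("site '", sites[bad[1L, 1L]], "' has a non-positive mean for ",
         "biomarker '", colnames(m)[bad[1L, 2L]],
         "'; the log-ratio is undefined", call. = FALSE)
  }
  # reference row first; remaining sites keep input order
  ord <- c(reference, setdiff(sites, reference))
  m <- m[ord, , drop = FALSE]
  Y <- sweep(log(m), 2L, log(m[reference, ]), `-`)
  Z <- Y
  for (j in colnames(Y)) {
    s <- stats::sd(Y[, j])
    Z[, j] <- if (is.finite(s) && s > 0) (Y[, j] - mean(Y[, j])) / s else 0
  }
  A <- sweep(Z, 2L, Z[reference, ], `-`)
  out <- list(sites = ord, biomarkers = colnames(m), reference = reference,
              Y = strip_smm(Y), Z = strip_smm(Z), A = strip_smm(A))
  class(out) <- "ibrv2_bdi"
  out
}

#' @export
print.ibrv2_bdi <- function(x, ...) {
  cat("<ibrv2_bdi> reference site '", x$reference, "'\nA parameters:\n",
      sep = "")
  print(round(x$A, 4), ...)
  invisible(x)
}

#' Compute the IBRv2 index
#'
#' Sums the absolute values of the A parameters across biomarkers per
#' site: IBRv2_i = sum_j |A_ij|. The reference site scores exactly 0 by
#' construction.
#'
#' @param x An `ibrv2_bdi` object, or a [biomarker_table()] (deviations are
#'   computed first, against `reference`).
#' @param reference,force Passed to [ibrv2_bdi()] when `x` is a raw table.
#' @return An object of class `ibrv2_result`: data.frame with columns
#'   `site` and `IBRv2` (reference site first), with the reference label in
#'   attribute `reference`.
#' @examples
#' tab <- data.frame(site = c("ref", "s1", "s2"),
#'                   cat = c(1, exp(1), exp(-1)),
#'                   gst = c(1, exp(1), exp(-1)),
#'                   ache = c(1, exp(1), exp(-1)))
#' ibrv2_index(biomarker_table(tab))  # 0, 3, 3
#' @export
ibrv2_index <- function(x, reference = NULL, force = FALSE) {
  bdi <- if (inherits(x, "ibrv2_bdi")) x else
    ibrv2_bdi(x, reference = reference, force = force)
  v <- rowSums(abs(bdi$A))
  out <- data.frame(site = bdi$sites, IBRv2 = unname(v),
                    stringsAsFactors = FALSE)
  attr(out, "reference") <- bdi$reference
  class(out) <- c("ibrv2_result", "data.frame")
  out
}

#' @export
print.ibrv2_result <- function(x, ...) {
  cat("<ibrv2_result> reference site '", attr(x, "reference"), "'\n", sep = "")
  df <- data.frame(site = x$site, IBRv2 = round(x$IBRv2, 4))
  print(df, row.names = FALSE, ...)
  invisible(x)
}
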