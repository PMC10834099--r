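#' Standardize site means for the IBR index
#'
#' First step of the revised Integrated Biomarker Response calculation.
#' Per biomarker j the site means m_ij are centered and scaled across sites
#' (sample SD, n-1 denominator): Y_ij = (m_ij - mean_i) / sd_i. The
#' direction coefficient then flips inhibited biomarkers, Z_ij = c_j * Y_ij,
#' and a per-biomarker shift makes the scores non-negative,
#' S_ij = Z_ij + |min_i Z_ij|, so the smallest site scores 0 on every
#' star-plot axis.
#'
#' @param x A [biomarker_table()] of raw replicate measurements, or a
#'   site-mean matrix as returned by [aggregate_site_means()].
#' @param coef Optional [coefficient_table()]; when `NULL` every biomarker
#'   uses coefficient `+1`.
#' @param force Waive the 3-9 biomarker-count rule during validation (the
#'   minimum-three-non-NA rule is never waived).
#' @return An object of class `ibr_std`: list with `sites`, `biomarkers`,
#'   `coefficients`, and the sites x biomarkers matrices `Y`, `Z`, `S`.
#' @examples
#' tab <- data.frame(site = c("S1", "S2", "S3"),
#'                   cat = c(1, 2, 3), gst = c(10, 30, 20), ache = c(5, 4, 6))
#' std <- ibr_std(biomarker_table(tab))
#' std$S
#' @export
ibr_std <- function(x, coef = NULL, force = FALSE) {
  m <- as_site_means(x, force = force)
  if (nrow(m) < 2L) stop("at least two sites are required", call. = FALSE)
  bmk <- colnames(m)
  cf <- align_coefficients(coef, bmk)
  Y <- m
  for (j in bmk) {
    s <- stats::sd(m[, j])
    if (!is.finite(s) || s == 0) {
      stop("biomarker '", j, "' has zero variance across site means; ",
           "it cannot be standardized", call. = FALSE)
    }
    Y[, j] <- (m[, j] - mean(m[, j])) / s
  }
  Z <- sweep(Y, 2L, cf, `*`)
  S <- sweep(Z, 2L, abs(apply(Z, 2L, min)), `+`)
  out <- list(sites = rownames(m), biomarkers = bmk, coefficients = cf,
              Y = strip_smm(Y), Z = strip_smm(Z), S = strip_smm(S))
  class(out) <- "ibr_std"
  out
}

strip_smm <- function(m) {
  class(m) <- setdiff(class(m), "site_mean_matrix")
  m
}

#' @export
print.ibr_std <- function(x, ...) {
  cat("<ibr_std> ", length(x$sites), " sites x ", length(x$biomarkers),
      " biomarkers\nS (standardized, shifted scores):\n", sep = "")
  print(round(x$S, 4), ...)
  invisible(x)
}

# all permutations of an integer vector, in lexicographic order
perms_int <- function(v) {
  n <- length(v)
  if (n <= 1L) return(list(v))
  out <- vector("list", factorial(n))
  idx <- 1L
  for (i in seq_len(n)) {
    for (p in perms_int(v[-i])) {
      out[[idx]] <- c(v[i], p)
      idx <- idx + 1L
    }
  }
  out
}

# TRUE if integer vector a is lexicographically <= b (equal lengths)
lex_leq <- function(a, b) {
  d <- which(a != b)
  if (length(d) == 0L) return(TRUE)
  a[d[1L]] < b[d[1L]]
}

#' Enumerate distinct circular biomarker arrangements
#'
#' The star-plot area depends on which biomarkers are adjacent, so the IBR
#' is averaged over all possible circular permutations of the k biomarkers.
#' Orderings that differ only by rotation or reflection trace the same
#' polygon and are enumerated once, giving (k-1)!/2 canonical arrangements.
#' Each arrangement starts at index 1 and is the lexicographically smaller
#' of itself and its reversal; the list is in lexicographic order.
#'
#' @param k Number of biomarkers, between 3 and 9.
#' @return List of integer vectors, each a permutation of `1:k`.
#' @examples
#' enumerate_arrangements(4)  # 3 arrangements
#' @export
enumerate_arrangements <- function(k) {
  if (length(k) != 1L || !is.finite(k) || k != as.integer(k) || k < 3L || k > 9L) {
    stop("`k` must be an integer between 3 and 9", call. = FALSE)
  }
  k <- as.integer(k)
  keep <- list()
  for (p in perms_int(2:k)) {
    if (lex_leq(p, rev(p))) keep[[length(keep) + 1L]] <- c(1L, p)
  }
  keep
}

#' Star-plot (radar) polygon area
#'
#' Area of the star plot whose i-th vertex lies at radius s_i on the i-th
#' of k equally spaced axes, with the biomarkers placed around the plot in
#' the order given by `arrangement`. With s the reordered scores and
#' s_(k+1) = s_1, the area is sum_i s_i * s_(i+1) * sin(2*pi/k) / 2 — the
#' sum of the k triangles between consecutive axes.
#'
#' @param scores Non-negative finite score vector of length k.
#' @param arrangement Permutation of `1:k` (default: identity order).
#' @return Non-negative scalar area.
#' @examples
#' star_area(c(1, 1, 1))          # equilateral triangle, 3*sqrt(3)/4
#' star_area(c(1, 2, 1, 2))       # 4
#' @export
star_area <- function(scores, arrangement = seq_along(scores)) {
  scores <- as.numeric(scores)
  k <- length(scores)
  if (k < 3L) stop("at least three scores are required", call. = FALSE)
  if (any(!is.finite(scores)) || any(scores < 0)) {
    stop("scores must be finite and non-negative", call. = FALSE)
  }
  if (length(arrangement) != k || !setequal(arrangement, seq_len(k))) {
    stop("`arrangement` must be a permutation of 1:", k, call. = FALSE)
  }
  s <- scores[arrangement]
  sum(s * c(s[-1L], s[1L])) * sin(2 * pi / k) / 2
}

#' Compute the IBR index
#'
#' Evaluates the star-plot area of each site's standardized scores for
#' every distinct circular arrangement of the biomarkers, and reports the
#' per-site mean and sample standard deviation over the arrangements —
#' the IBR value with its arrangement uncertainty. With k = 3 there is a
#' single arrangement and the SD is reported as 0.
#'
#' @param x An `ibr_std` object, or a [biomarker_table()] (standardized
#'   with all-`+1` coefficients first).
#' @param coef,force Passed to [ibr_std()] when `x` is a raw table.
#' @return An object of class `ibr_result`: list with `per_arrangement`
#'   (arrangements x sites area matrix, row names give the biomarker
#'   ordering), `mean` and `sd` (named per-site vectors), and
#'   `arrangements`.
#' @examples
#' tab <- data.frame(site = c("S1", "S2", "S3"),
#'                   cat = c(1, 2, 3), gst = c(10, 30, 20),
#'                   ache = c(5, 4, 6), ldh = c(100, 150, 120))
#' ibr_index(ibr_std(biomarker_table(tab)))
#' @export
ibr_index <- function(x, coef = NULL, force = FALSE) {
  std <- if (inherits(x, "ibr_std")) x else ibr_std(x, coef = coef, force = force)
  k <- length(std$biomarkers)
  if (k < 3L || k > 9L) {
    stop("the IBR is defined for three to nine biomarkers; got ", k,
         call. = FALSE)
  }
  arr <- enumerate_arrangements(k)
  areas <- matrix(NA_real_, nrow = length(arr), ncol = length(std$sites),
                  dimnames = list(
                    vapply(arr, function(a) paste(std$biomarkers[a],
                                                  collapse = "-"), ""),
                    std$sites))
  for (i in seq_along(arr)) {
    for (s in seq_along(std$sites)) {
      areas[i, s] <- star_area(std$S[s, ], arr[[i]])
    }
  }
  mu <- colMeans(areas)
  sdev <- if (nrow(areas) > 1L) apply(areas, 2L, stats::sd) else
    stats::setNames(rep(0, ncol(areas)), colnames(areas))
  out <- list(per_arrangement = areas, mean = mu, sd = sdev,
              arrangements = arr)
  class(out) <- "ibr_result"
  out
}

#' @export
print.ibr_result <- function(x, ...) {
  cat("<ibr_result> ", nrow(x$per_arrangement), " arrangement(s) x ",
      ncol(x$per_arrangement), " site(s)\nIBR (mean +/- SD over arrangements):\n",
      sep = "")
  print(data.frame(site = names(x$mean), IBR_mean = round(x$mean, 4),
                   IBR_sd = round(x$sd, 4), row.names = NULL), ...)
  invisible(x)
}

#' Per-site IBR summary table
#'
#' @param x An `ibr_result`.
#' @param ... Unused.
#' @return data.frame with columns `site`, `IBR_mean`, `IBR_sd` (full
#'   precision; rounding is left to the caller).
#' @export
as.data.frame.ibr_result <- function(x, ...) {
  data.frame(site = names(x$mean), IBR_mean = unname(x$mean),
             IBR_sd = unname(x$sd), stringsAsFactors = FALSE)
}
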