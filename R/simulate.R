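#' Simulate a multi-site enzyme-activity biomarker dataset
#'
#' Deterministic generator of example data in the shape both indexes
#' consume: a biomarker table of replicate enzyme activities per site and
#' the matching coefficient table. The measurement model is multiplicative:
#' value(site i, biomarker j, replicate r) = baseline_j * effect_ij *
#' lognormal noise with coefficient of variation `cv` (the noise has unit
#' mean, so site means converge to baseline * effect). The first site is
#' the designated reference: its effects are all 1. Enzyme activities are
#' positive by construction, which keeps the IBRv2 log-ratio defined for
#' every generated value.
#'
#' The defaults emulate a typical 4-site biomonitoring design with five
#' enzymatic biomarkers — catalase (cat), glutathione S-transferase (gst),
#' acetylcholinesterase (ache), lactate dehydrogenase (ldh) and superoxide
#' dismutase (sod) — where ache is inhibited by exposure (direction -1) and
#' the others are induced (+1), along a geometric exposure gradient away
#' from the reference site.
#'
#' @param n_sites Number of sites (>= 2); first site is the reference.
#' @param n_biomarkers Number of biomarkers (3-9).
#' @param replicates Replicates per site (>= 1).
#' @param baselines Positive baseline level per biomarker (recycled from
#'   the built-in enzyme activities when `NULL`).
#' @param effects `n_sites x n_biomarkers` matrix of positive multiplicative
#'   effects; row 1 (the reference) must be all 1. `NULL` builds the default
#'   gradient `exp(direction_j * gradient * (i - 1))`.
#' @param gradient Log-scale step of the default effect gradient per site.
#' @param cv Replicate noise coefficient of variation (>= 0; 0 disables
#'   noise).
#' @param miss_prob Probability that an entry is masked missing, in
#'   `[0, 1)`. Masking never removes values below the validity thresholds:
#'   every site/biomarker cell keeps at least one replicate and every
#'   biomarker column at least three values overall.
#' @param directions Vector of `+1`/`-1` effect directions per biomarker.
#' @param seed Optional integer seed; identical seeds give identical output.
#' @param site_labels,biomarker_labels Optional label overrides.
#' @return List with `biomarkers` (a [biomarker_table()]), `coefficients`
#'   (a [coefficient_table()]), and `site_means_expected` (the noise-free
#'   sites x biomarkers matrix baseline * effect).
#' @examples
#' sim <- simulate_biomarkers(seed = 1)
#' head(sim$biomarkers)
#' @export
simulate_biomarkers <- function(n_sites = 4, n_biomarkers = 5, replicates = 8,
                                baselines = NULL, effects = NULL,
                                gradient = 0.4, cv = 0.1, miss_prob = 0,
                                directions = NULL, seed = NULL,
                                site_labels = NULL, biomarker_labels = NULL) {
  if (n_sites < 2L) stop("`n_sites` must be >= 2", call. = FALSE)
  if (n_biomarkers < 3L || n_biomarkers > 9L) {
    stop("`n_biomarkers` must be between 3 and 9", call. = FALSE)
  }
  if (replicates < 1L) stop("`replicates` must be >= 1", call. = FALSE)
  if (cv < 0) stop("`cv` must be >= 0", call. = FALSE)
  if (miss_prob < 0 || miss_prob >= 1) {
    stop("`miss_prob` must be in [0, 1)", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(as.integer(seed))

  default_enzymes <- c("cat", "gst", "ache", "ldh", "sod",
                       "gpx", "gr", "mda", "ef")
  default_baselines <- c(18.2, 95.4, 31.7, 240, 12.5, 55, 28, 4.6, 150)
  default_directions <- c(1, 1, -1, 1, 1, 1, 1, 1, -1)

  bmk <- if (is.null(biomarker_labels))
    default_enzymes[seq_len(n_biomarkers)] else biomarker_labels
  sites <- if (is.null(site_labels))
    paste0("S", seq_len(n_sites) - 1L) else site_labels
  if (is.null(baselines)) baselines <- default_baselines[seq_len(n_biomarkers)]
  if (any(baselines <= 0)) stop("`baselines` must be positive", call. = FALSE)
  if (is.null(directions)) directions <- default_directions[seq_len(n_biomarkers)]
  if (!all(directions %in% c(-1, 1))) {
    stop("`directions` must be +1 or -1", call. = FALSE)
  }
  if (is.null(effects)) {
    # exposure gradient: induced biomarkers rise, inhibited ones fall,
    # geometrically with distance from the reference site
    effects <- outer(seq_len(n_sites) - 1L, directions,
                     function(i, d) exp(d * gradient * i))
  }
  effects <- as.matrix(effects)
  if (!all(dim(effects) == c(n_sites, n_biomarkers))) {
    stop("`effects` must be an n_sites x n_biomarkers matrix", call. = FALSE)
  }
  if (any(effects <= 0)) stop("`effects` must be positive", call. = FALSE)
  if (any(effects[1L, ] != 1)) {
    stop("reference-site effects (row 1) must all equal 1", call. = FALSE)
  }

  mu <- sweep(effects, 2L, baselines, `*`)  # expected site means
  rownames(mu) <- sites
  colnames(mu) <- bmk
  n <- n_sites * replicates
  site_col <- rep(sites, each = replicates)
  vals <- matrix(NA_real_, nrow = n, ncol = n_biomarkers,
                 dimnames = list(NULL, bmk))
  if (cv > 0) {
    sdlog <- sqrt(log1p(cv^2))
    for (j in seq_len(n_biomarkers)) {
      m_rep <- rep(mu[, j], each = replicates)
      vals[, j] <- stats::rlnorm(n, meanlog = log(m_rep) - sdlog^2 / 2,
                                 sdlog = sdlog)
    }
  } else {
    for (j in seq_len(n_biomarkers)) {
      vals[, j] <- rep(mu[, j], each = replicates)
    }
  }

  if (miss_prob > 0) {
    mask <- matrix(stats::runif(n * n_biomarkers) < miss_prob, nrow = n)
    # repair: keep >= 1 replicate per site x biomarker cell ...
    for (j in seq_len(n_biomarkers)) {
      for (s in sites) {
        rows <- which(site_col == s)
        if (all(mask[rows, j])) mask[rows[1L], j] <- FALSE
      }
      # ... and >= 3 observed values per biomarker column
      short <- 3L - sum(!mask[, j])
      if (short > 0L) {
        mask[which(mask[, j])[seq_len(short)], j] <- FALSE
      }
    }
    vals[mask] <- NA_real_
  }

  tab <- data.frame(site = site_col, stringsAsFactors = FALSE)
  for (j in seq_len(n_biomarkers)) tab[[bmk[j]]] <- vals[, j]
  list(biomarkers = biomarker_table(tab),
       coefficients = coefficient_table(bmk, directions),
       site_means_expected = mu)
}
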