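# Independent oracles and fixture builders. These deliberately do not call
# the package's own geometry/combinatorics code paths.

# Shoelace (surveyor's) polygon area on Cartesian vertices at radius s_i
# and angle 2*pi*(i-1)/k.
shoelace_area <- function(scores, arrangement = seq_along(scores)) {
  k <- length(scores)
  s <- scores[arrangement]
  th <- 2 * pi * (seq_len(k) - 1L) / k
  x <- s * cos(th)
  y <- s * sin(th)
  xn <- c(x[-1L], x[1L])
  yn <- c(y[-1L], y[1L])
  abs(sum(x * yn - xn * y)) / 2
}

# all permutations of a vector (brute force, independent of the package)
oracle_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (p in oracle_perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  }
  out
}

# canonical string of a cyclic ordering under rotation AND reflection
necklace_canon <- function(p) {
  k <- length(p)
  best <- NULL
  for (q in list(p, rev(p))) {
    for (r in 0:(k - 1L)) {
      w <- c(q[seq_len(k) > r], q[seq_len(r)])
      s <- paste(w, collapse = "-")
      if (is.null(best) || s < best) best <- s
    }
  }
  best
}

# number of distinct necklaces of 1:k by exhaustive dedup of all k! orderings
brute_necklace_count <- function(k) {
  length(unique(vapply(oracle_perms(seq_len(k)), necklace_canon, "")))
}

# replicate table over 2+ sites with fully observed values
make_table <- function(n_sites = 4, k = 5, reps = 3, seed = 1) {
  set.seed(seed)
  sites <- paste0("S", seq_len(n_sites))
  df <- data.frame(site = rep(sites, each = reps), stringsAsFactors = FALSE)
  for (j in seq_len(k)) {
    df[[paste0("bmk", j)]] <- round(stats::runif(n_sites * reps, 1, 100), 3)
  }
  biomarker_table(df)
}

write_temp_csv <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  path
}
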