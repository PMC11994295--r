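# shared fixtures and independent oracles

# one canonical occurrence row with overridable fields
make_record <- function(...) {
  rec <- list(species = "Synthogenus speca", lat = 1.5, lon = 1.5,
              year = 2000L, event_date = NA_character_,
              collector = "J. Smith", locality = "Site A",
              count = 1L, country = NA_character_, source = "gbif",
              valid_coords = TRUE)
  over <- list(...)
  rec[names(over)] <- over
  as.data.frame(rec, stringsAsFactors = FALSE)
}

make_records <- function(...) {
  rows <- list(...)
  do.call(rbind, rows)
}

# exact expected richness after k records: hypergeometric rarefaction,
# E[S(k)] = sum_s (1 - choose(N - n_s, k) / choose(N, k)).
# Independent of the package's permutation-averaging implementation.
rarefaction_oracle <- function(species) {
  n_s <- table(species)
  N <- length(species)
  vapply(seq_len(N), function(k) {
    sum(1 - choose(N - n_s, k) / choose(N, k))
  }, numeric(1))
}

# brute-force two-sample KS statistic: sup of |ECDF difference| over the
# pooled sample points
ks_oracle <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  max(abs(vapply(pts, function(x) mean(a <= x) - mean(b <= x), numeric(1))))
}

# random point on the probability simplex
random_simplex <- function(k) {
  x <- stats::rexp(k)
  x / sum(x)
}

write_occurrence_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, na = "")
  path
}
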