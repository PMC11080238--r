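`%||%` <- function(a, b) if (is.null(a)) b else a

# class-stratified fold assignment, deterministic under seed
stratified_folds <- function(y, k, seed = 1L) {
  foldid <- integer(length(y))
  withr::with_seed(seed, {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      foldid[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  foldid
}

# stratified train/test index split
stratified_split <- function(y, test_fraction, seed = 1L) {
  test_idx <- integer(0)
  withr::with_seed(seed, {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      n_test <- max(1L, round(test_fraction * length(idx)))
      test_idx <- c(test_idx, sample(idx, n_test))
    }
  })
  list(train = setdiff(seq_along(y), test_idx), test = sort(test_idx))
}
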