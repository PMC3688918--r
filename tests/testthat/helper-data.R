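# Compact builders for hand-sized fixtures.

# injection table with explicit intensity matrix (features x injections);
# roles/classes derived from sample ids: NA sample_id = blank.
tiny_table <- function(intensity, sample_ids, rt = NULL, mz = NULL,
                       is_channel = NULL) {
  p <- nrow(intensity)
  if (is.null(rt)) rt <- seq(0.5, by = 0.5, length.out = p)
  if (is.null(mz)) mz <- seq(100, by = 37.1111, length.out = p)
  features <- data.frame(feature_id = hypoxmet::feature_id(rt, mz),
                         rt = rt, mz = mz)
  n <- ncol(intensity)
  rep_idx <- stats::ave(seq_len(n), sample_ids,
                        FUN = seq_along)
  injections <- data.frame(
    injection_id = paste0("inj", seq_len(n)),
    sample_id = sample_ids,
    replicate_index = rep_idx,
    role = ifelse(is.na(sample_ids), "blank", "sample"),
    class_label = ifelse(is.na(sample_ids), NA,
                         ifelse(grepl("^H", sample_ids), "hypoxia",
                                "normoxia")),
    run_order = seq_len(n), stringsAsFactors = FALSE)
  hypoxmet::injection_table(features, injections, intensity, is_channel)
}

# two-class matrix with a strong discriminant direction spread over the
# first n_signal features (a lone informative feature cannot beat the
# chance-correlation weight of many noise features at n = 10)
make_separated <- function(n_per_class = 5, p = 12, delta = 3, seed = 42,
                           n_signal = 4) {
  set.seed(seed)
  x <- matrix(rnorm(2 * n_per_class * p), 2 * n_per_class, p)
  sig <- seq_len(n_signal)
  x[seq_len(n_per_class), sig] <- x[seq_len(n_per_class), sig] + delta
  y <- rep(c(0, 1), each = n_per_class)
  list(x = x, y = y)
}

small_null_config <- function(n_discriminant = 0L)
  hypoxmet::generator_config(n_features = 60L, n_blank_features = 20L,
                             n_lowfreq_features = 20L,
                             n_discriminant = n_discriminant)
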