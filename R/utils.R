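# Internal helpers shared across modules.

# Round half away from zero (R's round() is banker's rounding).
round_half_up <- function(x) floor(x + 0.5)

# Deterministic derived seed, kept inside 32-bit integer range.
child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 10007 + as.numeric(offset)) %% 2147483629)
}

# Exact integer apportionment of n among length(props) cells
# (largest-remainder / Hamilton rounding). sum(result) == n always.
largest_remainder <- function(n, props) {
  target <- n * props
  base <- floor(target)
  short <- n - sum(base)
  if (short > 0) {
    extra <- order(target - base, decreasing = TRUE)[seq_len(short)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

config_error <- function(field, msg) {
  abort(sprintf("invalid configuration: `%s` %s", field, msg),
        class = "screen_config_error")
}

stop_if_not_prob <- function(x, field) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1)) {
    config_error(field, "must be a probability in [0, 1]")
  }
}

# Inverse-class-frequency observation weights, mean 1.
inverse_freq_weights <- function(y) {
  tab <- table(y)
  w <- length(y) / (length(tab) * as.numeric(tab[as.character(y)]))
  as.numeric(w)
}

# Seeded undersampling of the majority class down to a 1:1 ratio.
undersample_index <- function(y, seed) {
  tab <- table(y)
  m <- min(tab)
  set.seed(seed)
  idx <- unlist(lapply(names(tab), function(cl) {
    members <- which(y == as.numeric(cl))
    if (length(members) > m) sort(sample(members, m)) else members
  }), use.names = FALSE)
  sort(idx)
}
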