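# Shared fixtures, built in code at test time.

# two-atom topology with a single bond
mini_topology <- function() {
  chromophore_topology(
    tibble::tibble(atom = c("C13", "C14", "C15"),
                   ring = c("C", "C", "bridge")),
    tibble::tibble(atom_a = c("C13", "C14"), atom_b = c("C14", "C15")))
}

# square 6x6 spec used throughout the recovery tests
square_spec <- function(seed = 1, sigma_shift_ppm = 0, ...) {
  synthetic_spec(sigma_shift_ppm = sigma_shift_ppm, seed = seed, ...)
}

# the reference bond-change pattern (pm), at the scale reported for
# photoproduct formation (tens of pm on the ring C/D chain)
truth_dd <- function(spec = square_spec()) {
  stats::setNames(c(-17, 5, -14, 0, 2, 16), spec$bonds)
}

# hand-rolled OLS oracle, textbook formulas only
ols_oracle <- function(x, y) {
  n <- length(x)
  xb <- mean(x); yb <- mean(y)
  sxx <- sum((x - xb)^2)
  slope <- sum((x - xb) * (y - yb)) / sxx
  intercept <- yb - slope * xb
  e <- y - intercept - slope * x
  se <- sqrt(sum(e^2) / (n - 2) / sxx)
  tval <- slope / se
  list(slope = slope, intercept = intercept, se = se,
       p = 2 * stats::pt(abs(tval), df = n - 2, lower.tail = FALSE),
       r = sum((x - xb) * (y - yb)) / sqrt(sxx * sum((y - yb)^2)))
}

# brute-force block means
block_means_oracle <- function(v, b) {
  nb <- length(v) %/% b
  vapply(seq_len(nb), function(i) mean(v[((i - 1) * b + 1):(i * b)]),
         numeric(1))
}

# order-pattern tibble for conjugation tests
order_pattern <- function(orders, bonds = NULL, state = "test") {
  if (is.null(bonds))
    bonds <- bond_label(paste0("C", 11 + seq_along(orders)),
                        paste0("C", 12 + seq_along(orders)))
  structure(tibble::tibble(state = state, bond = bonds, order = orders),
            class = c("bond_order_pattern", class(tibble::tibble())))
}
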