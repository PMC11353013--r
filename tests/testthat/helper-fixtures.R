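# shared fixtures: small dose grids and a 1:3 dilution series
dil3 <- function(top = 10, n = 9) sort(top / 3^(seq_len(n) - 1))

ll_fun <- function(d, upper, lower, ec50, h) {
  out <- lower + (upper - lower) / (1 + (d / ec50)^h)
  out[d == 0] <- upper
  out
}

# response matrix with margins in row 1 / col 1 built from margin vectors
response_with_margins <- function(ra, rb, combo) {
  r <- combo
  r[, 1] <- ra
  r[1, ] <- rb
  r
}
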