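## shared fixtures and independent oracles

## noiseless profile on the standard grid
noiseless_profile <- function(a = 550, b = 10, plateau = 0,
                              temps = seq(37, 67, length.out = 10)) {
  data.frame(temperature_c = temps,
             rel_abundance = melt_sigmoid(temps, a, b, plateau))
}

## independent brute-force BH step-up: adjusted p_i = min over j with
## p_(j) >= p_(i) of m * p_(j) / j, capped at 1
bh_brute_force <- function(p) {
  m <- length(p)
  ord <- order(p)
  ranked <- p[ord]
  stepped <- pmin(1, m * ranked / seq_len(m))
  adj <- rev(cummin(rev(stepped)))
  out <- numeric(m)
  out[ord] <- adj
  out
}

## independent bisection root-finder for f(T) = 0.5 on the melting sigmoid
tm_bisection <- function(a, b, plateau, lower = 1, upper = 5000,
                         tol = 1e-9) {
  f <- function(T) melt_sigmoid(T, a, b, plateau) - 0.5
  if (f(lower) < 0 || f(upper) > 0) return(NA_real_)
  while (upper - lower > tol) {
    mid <- (lower + upper) / 2
    if (f(mid) > 0) lower <- mid else upper <- mid
  }
  (lower + upper) / 2
}

## per-node degree recount straight from an edge data frame (undirected,
## deduplicated, loops dropped) without igraph
degree_brute_force <- function(edges) {
  a <- toupper(trimws(edges[[1]])); b <- toupper(trimws(edges[[2]]))
  keep <- a != b
  a <- a[keep]; b <- b[keep]
  key <- ifelse(a < b, paste(a, b), paste(b, a))
  dedup <- !duplicated(key)
  a <- a[dedup]; b <- b[dedup]
  tab <- table(c(a, b))
  setNames(as.integer(tab), names(tab))
}

read_fixture <- function(file) {
  read_compound_table(tppshift_example(file))
}
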