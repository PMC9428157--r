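# Independent brute-force oracles used to cross-check the implementation.
# These are deliberately naive (explicit loops, no shared code with R/).

# Alpha diversity computed step by step from first principles.
oracle_alpha <- function(counts) {
  counts <- counts[counts > 0]
  N <- 0; for (c in counts) N <- N + c
  sobs <- length(counts)
  n1 <- 0; n2 <- 0
  for (c in counts) {
    if (c == 1) n1 <- n1 + 1
    if (c == 2) n2 <- n2 + 1
  }
  chao1 <- sobs + n1 * (n1 - 1) / (2 * (n2 + 1))
  shannon <- 0; simpson <- 0
  for (c in counts) {
    p <- c / N
    shannon <- shannon - p * log(p)
    simpson <- simpson + p * p
  }
  goods <- 1 - n1 / N
  # ACE, rare cutoff 10
  s_abund <- 0; s_rare <- 0; n_rare <- 0
  fi <- rep(0, 10)
  for (c in counts) {
    if (c > 10) s_abund <- s_abund + 1
    else { s_rare <- s_rare + 1; n_rare <- n_rare + c; fi[c] <- fi[c] + 1 }
  }
  if (s_rare == 0) {
    ace <- s_abund
  } else {
    c_ace <- 1 - fi[1] / n_rare
    if (c_ace <= 0) {
      ace <- chao1
    } else {
      num <- 0
      for (i in 1:10) num <- num + i * (i - 1) * fi[i]
      g2 <- s_rare / c_ace * num / (n_rare * (n_rare - 1)) - 1
      if (g2 < 0) g2 <- 0
      ace <- s_abund + s_rare / c_ace + fi[1] / c_ace * g2
    }
  }
  c(sobs = sobs, chao1 = chao1, ace = ace, shannon = shannon,
    simpson = simpson, goods_coverage = goods)
}

oracle_bray <- function(x, y) {
  num <- 0; den <- 0
  for (i in seq_along(x)) {
    num <- num + abs(x[i] - y[i])
    den <- den + x[i] + y[i]
  }
  num / den
}

# Closed-form OLS via the normal equations.
oracle_ols <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  sxx <- sum(x * x); sxy <- sum(x * y)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx * sx)
  intercept <- (sy - slope * sx) / n
  c(slope = slope, intercept = intercept)
}

# Minimal-rotation Procrustes error between two configurations (centered,
# optimal rotation/reflection via SVD, no scaling of relative geometry).
procrustes_error <- function(x, y) {
  x <- scale(x, scale = FALSE); y <- scale(y, scale = FALSE)
  s <- svd(t(y) %*% x)
  rot <- s$u %*% t(s$v)
  sc <- sum(s$d) / sum(x^2)
  sqrt(sum((y - sc * x %*% rot)^2))
}

# PERMANOVA pseudo-F computed independently (explicit loops).
oracle_pseudo_f <- function(d, groups) {
  n <- nrow(d)
  ss_t <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) ss_t <- ss_t + d[i, j]^2
  ss_t <- ss_t / n
  ss_w <- 0
  for (lev in unique(groups)) {
    idx <- which(groups == lev)
    if (length(idx) > 1) {
      s <- 0
      for (a in 1:(length(idx) - 1)) for (b in (a + 1):length(idx))
        s <- s + d[idx[a], idx[b]]^2
      ss_w <- ss_w + s / length(idx)
    }
  }
  a <- length(unique(groups))
  ((ss_t - ss_w) / (a - 1)) / (ss_w / (n - a))
}

# Small, fast experiment configuration for pipeline tests.
small_config <- function(...) {
  synthetic_config(n_replicates = 2, seq_depth = 2000,
                   ddpcr_n_droplets = 5000, ...)
}

# Single-group template with a given phylum split, for targeted community
# simulations.
flat_template <- function(group = "IP", n_firmicutes = 10, n_other = 10,
                          p_firmicutes = 0.8) {
  n <- n_firmicutes + n_other
  data.frame(
    group = group,
    phylum = rep(c("Firmicutes", "Proteobacteria"),
                 c(n_firmicutes, n_other)),
    family = "FamilyA",
    genus = paste0("Genus", seq_len(n)),
    otu_id = sprintf("OTU%04d", seq_len(n)),
    prop = c(rep(p_firmicutes / n_firmicutes, n_firmicutes),
             rep((1 - p_firmicutes) / n_other, n_other)),
    stringsAsFactors = FALSE
  )
}
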