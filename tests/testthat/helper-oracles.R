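# Independent oracles, coded directly from first principles / the literal
# formula definitions, used to cross-check the package implementations.

# Brute-force GLCM: enumerate ALL ordered voxel pairs and count those
# separated by exactly `offset`, both endpoints inside the mask.
brute_glcm <- function(levels, G, offset) {
  dm <- dim(levels)
  idx <- which(!is.na(levels))
  co <- cbind((idx - 1) %% dm[1] + 1,
              ((idx - 1) %/% dm[1]) %% dm[2] + 1,
              (idx - 1) %/% (dm[1] * dm[2]) + 1)
  lv <- levels[idx]
  n <- length(idx)
  cnt <- matrix(0, G, G)
  for (a in seq_len(n)) {
    d1 <- co[, 1] - co[a, 1]
    d2 <- co[, 2] - co[a, 2]
    d3 <- co[, 3] - co[a, 3]
    hit <- which(d1 == offset[1] & d2 == offset[2] & d3 == offset[3])
    for (b in hit) cnt[lv[a], lv[b]] <- cnt[lv[a], lv[b]] + 1
  }
  cnt
}

# Literal-formula Haralick oracle: plain double loops over matrix cells,
# all entropies via natural log then converted to bits.
haralick_oracle <- function(P) {
  G <- nrow(P)
  lb <- function(x) log(x) / log(2)
  px <- numeric(G); py <- numeric(G)
  for (i in 1:G) for (j in 1:G) {
    px[i] <- px[i] + P[i, j]
    py[j] <- py[j] + P[i, j]
  }
  mux <- sum((1:G) * px); muy <- sum((1:G) * py)
  sx <- sqrt(sum(((1:G) - mux)^2 * px)); sy <- sqrt(sum(((1:G) - muy)^2 * py))
  ent <- 0; asm <- 0; contrast <- 0; hom <- 0; idm <- 0; corr_num <- 0
  shade <- 0; prom <- 0
  psum <- numeric(2 * G); pdiff <- numeric(G)  # psum[k] = p_{x+y}(k), k=2..2G
  for (i in 1:G) for (j in 1:G) {
    p <- P[i, j]
    if (p > 0) ent <- ent - p * lb(p)
    asm <- asm + p^2
    contrast <- contrast + (i - j)^2 * p
    hom <- hom + p / (1 + abs(i - j))
    idm <- idm + p / (1 + (i - j)^2)
    corr_num <- corr_num + i * j * p
    shade <- shade + (i + j - mux - muy)^3 * p
    prom <- prom + (i + j - mux - muy)^4 * p
    psum[i + j] <- psum[i + j] + p
    pdiff[abs(i - j) + 1] <- pdiff[abs(i - j) + 1] + p
  }
  correlation <- if (sx > 0 && sy > 0) (corr_num - mux * muy) / (sx * sy) else 1
  sa <- 0; se <- 0
  for (k in 2:(2 * G)) {
    sa <- sa + k * psum[k]
    if (psum[k] > 0) se <- se - psum[k] * lb(psum[k])
  }
  sv <- 0
  for (k in 2:(2 * G)) sv <- sv + (k - sa)^2 * psum[k]
  da <- 0; de <- 0
  for (k in 0:(G - 1)) {
    da <- da + k * pdiff[k + 1]
    if (pdiff[k + 1] > 0) de <- de - pdiff[k + 1] * lb(pdiff[k + 1])
  }
  dv <- 0
  for (k in 0:(G - 1)) dv <- dv + (k - da)^2 * pdiff[k + 1]
  hx <- 0
  for (i in 1:G) if (px[i] > 0) hx <- hx - px[i] * lb(px[i])
  hy <- 0
  for (j in 1:G) if (py[j] > 0) hy <- hy - py[j] * lb(py[j])
  hxy1 <- 0; hxy2 <- 0
  for (i in 1:G) for (j in 1:G) {
    q <- px[i] * py[j]
    if (P[i, j] > 0 && q > 0) hxy1 <- hxy1 - P[i, j] * lb(q)
    if (q > 0) hxy2 <- hxy2 - q * lb(q)
  }
  imc1 <- if (max(hx, hy) > 0) (ent - hxy1) / max(hx, hy) else 0
  # base-invariant: exponent uses entropies in nats
  imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - ent) * log(2))))
  c(entropy = ent, homogeneity = hom, contrast = contrast,
    correlation = correlation, angular_second_moment = asm,
    difference_entropy = de, difference_variance = dv,
    inverse_difference_moment = idm, sum_average = sa, sum_entropy = se,
    sum_variance = sv, cluster_prominence = prom, cluster_shade = shade,
    maximum_probability = max(P), imc1 = imc1, imc2 = imc2)
}

# AUC by exhaustive pair counting: concordant + half of tied pairs.
auc_oracle <- function(values, labels) {
  labels <- as.logical(labels)
  pos <- values[labels]; neg <- values[!labels]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Two-group log-rank oracle: observed minus hypergeometric-expected events
# at each distinct event time.
logrank_oracle <- function(times, events, group) {
  group <- as.character(group)
  g1 <- unique(group)[1]
  ts <- sort(unique(times[events == 1]))
  O <- 0; E <- 0; V <- 0
  for (t in ts) {
    at_risk <- times >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == g1)
    d <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & group == g1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  stat <- if (V > 0) (O - E)^2 / V else 0
  list(statistic = stat, p_value = stats::pchisq(stat, 1, lower.tail = FALSE))
}

# Kendall tau-b by exhaustive pair enumeration:
# (C - D) / sqrt((n0 - n_tied_x)(n0 - n_tied_y)).
taub_oracle <- function(x, y) {
  n <- length(x)
  C <- 0; D <- 0; tx <- 0; ty <- 0; n0 <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    n0 <- n0 + 1
    dx <- sign(x[j] - x[i]); dy <- sign(y[j] - y[i])
    if (dx == 0) tx <- tx + 1
    if (dy == 0) ty <- ty + 1
    if (dx != 0 && dy != 0) {
      if (dx == dy) C <- C + 1 else D <- D + 1
    }
  }
  (C - D) / sqrt((n0 - tx) * (n0 - ty))
}

# Coarse-to-fine grid search of the 2-parameter logistic log-likelihood.
grid_logistic <- function(feature, outcome) {
  ll <- function(b0, b1) {
    eta <- b0 + b1 * feature
    sum(outcome * eta - log1p(exp(eta)))
  }
  ctr <- c(0, 0); width <- c(8, 8)
  for (pass in 1:12) {
    b0s <- seq(ctr[1] - width[1], ctr[1] + width[1], length.out = 21)
    b1s <- seq(ctr[2] - width[2], ctr[2] + width[2], length.out = 21)
    vals <- outer(b0s, b1s, Vectorize(ll))
    w <- which(vals == max(vals), arr.ind = TRUE)[1, ]
    ctr <- c(b0s[w[1]], b1s[w[2]])
    width <- width / 5
  }
  ctr
}

# Hand product-limit estimator (events before censorings at tied times).
km_oracle <- function(times, events) {
  ts <- sort(unique(times[events == 1]))
  s <- 1
  out <- numeric(length(ts))
  for (k in seq_along(ts)) {
    n <- sum(times >= ts[k])
    d <- sum(times == ts[k] & events == 1)
    s <- s * (1 - d / n)
    out[k] <- s
  }
  data.frame(time = ts, surv = out)
}
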