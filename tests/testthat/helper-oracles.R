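# Independent oracles used across the suite. Each is a direct, brute-force
# implementation of the defining formula, kept free of the package's own
# code paths.

# mean silhouette width by the direct formula: for point i with cluster C(i),
# a(i) = mean d(i, j) over j in C(i) \ {i}; b(i) = min over other clusters of
# mean d(i, j); s(i) = (b - a) / max(a, b); singleton clusters get s = 0.
oracleSilhouette <- function(x, labels) {
  d <- as.matrix(dist(x))
  n <- nrow(d)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    own <- setdiff(own, i)
    if (length(own) == 0L) { s[i] <- 0; next }
    a <- mean(d[i, own])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(cl) {
      mean(d[i, labels == cl])
    }, numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# Mann-Whitney AUC by explicit pair counting (ties count half)
oracleAUC <- function(score, label) {
  pos <- score[as.logical(label)]
  neg <- score[!as.logical(label)]
  if (length(pos) == 0L || length(neg) == 0L) return(NA_real_)
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# product-limit estimator by direct recursion; returns steps at event times
oracleKM <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  surv <- numeric(length(ts))
  s <- 1
  for (i in seq_along(ts)) {
    atRisk <- sum(time >= ts[i])
    d <- sum(time == ts[i] & event == 1)
    s <- s * (1 - d / atRisk)
    surv[i] <- s
  }
  data.frame(time = ts, survival = surv)
}

# two-group log-rank statistic by direct O-E / hypergeometric-variance sums
oracleLogrank <- function(time, event, group) {
  g <- as.integer(factor(group))
  ts <- sort(unique(time[event == 1]))
  O <- 0; E <- 0; V <- 0
  for (t in ts) {
    n1 <- sum(time >= t & g == 1); n2 <- sum(time >= t & g == 2)
    N <- n1 + n2
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g == 1)
    O <- O + d1
    E <- E + d * n1 / N
    if (N > 1) V <- V + d * (N - d) * n1 * n2 / (N^2 * (N - 1))
  }
  chisq <- (O - E)^2 / V
  list(chisq = chisq, p = pchisq(chisq, 1, lower.tail = FALSE))
}

# rigid transform of a point set by plain trigonometry (degrees, CCW,
# rotation about `center`, then translation)
oraclePoint <- function(p, dx, dy, theta, center = c(0, 0)) {
  th <- theta * pi / 180
  x <- p[1] - center[1]; y <- p[2] - center[2]
  c(cos(th) * x - sin(th) * y + center[1] + dx,
    sin(th) * x + cos(th) * y + center[2] + dy)
}

# exhaustive integer-shift Dice search (no FFT) for small masks
oracleBestShift <- function(fixed, moving, maxShift) {
  best <- list(dx = 0, dy = 0, score = -1)
  for (dx in -maxShift:maxShift) for (dy in -maxShift:maxShift) {
    shifted <- matrix(0L, nrow(moving), ncol(moving))
    rows <- seq_len(nrow(moving)) + dy
    cols <- seq_len(ncol(moving)) + dx
    okR <- rows >= 1 & rows <= nrow(moving)
    okC <- cols >= 1 & cols <= ncol(moving)
    shifted[rows[okR], cols[okC]] <- moving[okR, okC]
    sc <- tilePheno::diceOverlap(fixed, shifted)
    if (sc > best$score) best <- list(dx = dx, dy = dy, score = sc)
  }
  best
}

# lazily built, cached 5000-tile planted table shared by the end-to-end
# recovery checks (built once per test run)
.accCache <- new.env()
acc5000 <- function() {
  if (is.null(.accCache$x)) {
    out <- generateTileTable(defaultProfiles(),
                             c(Classical = 1250, Intermediate = 1250,
                               Basal.MUC16 = 1250, Basal.S100A2 = 1250),
                             seed = 42)
    cfg <- analysisConfig(seed = 42)
    tt <- filterTiles(out$tileTable, cfg)
    f <- preprocessFeatures(tt, cfg)
    .accCache$x <- list(out = out, cfg = cfg, tt = tt, f = f)
  }
  .accCache$x
}

# small default-catalog tile table shared by clustering tests
makePlantedTiles <- function(nPer = 150, seed = 7, concentration = 50) {
  generateTileTable(defaultProfiles(concentration),
                    c(Classical = nPer, Intermediate = nPer,
                      Basal.MUC16 = nPer, Basal.S100A2 = nPer),
                    seed = seed)
}

# agreement between fitted labels and planted labels (names already matched
# by the rule-based naming, so this is plain equality)
labelAgreement <- function(labels, truth) {
  mean(labels[names(truth)] == truth)
}
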