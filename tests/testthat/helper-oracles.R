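# Independent scalar oracles used by both the unit suites and the
# acceptance suite. Written directly from the published bandings and
# textbook definitions — deliberately not sharing code with the package.

# integer bands (e.g. heart rate 101-110) extended to continuous inputs as
# half-open intervals: [101, 111) scores 1, [111, 130) scores 2, ...
mews_oracle <- function(sbp, hr, rr, temp, avpu) {
  s <- 0
  s <- s + if (sbp < 71) 3 else if (sbp < 81) 2 else if (sbp < 101) 1
    else if (sbp < 200) 0 else 2
  s <- s + if (hr < 41) 2 else if (hr < 51) 1 else if (hr < 101) 0
    else if (hr < 111) 1 else if (hr < 130) 2 else 3
  s <- s + if (rr < 9) 2 else if (rr < 15) 0 else if (rr < 21) 1
    else if (rr < 30) 2 else 3
  s <- s + if (temp < 35) 2 else if (temp < 38.5) 0 else 2
  s + avpu
}

sofa_oracle <- function(pf, plt, bili, map, vaso, gcs, cr) {
  s <- 0
  s <- s + if (pf >= 400) 0 else if (pf >= 300) 1 else if (pf >= 200) 2
    else if (pf >= 100) 3 else 4
  s <- s + if (plt >= 150) 0 else if (plt >= 100) 1 else if (plt >= 50) 2
    else if (plt >= 20) 3 else 4
  s <- s + if (bili < 1.2) 0 else if (bili < 2) 1 else if (bili < 6) 2
    else if (bili < 12) 3 else 4
  s <- s + if (vaso > 0) { if (map < 70) 4 else 3 } else if (map < 70) 1 else 0
  s <- s + if (gcs >= 15) 0 else if (gcs >= 13) 1 else if (gcs >= 10) 2
    else if (gcs >= 6) 3 else 4
  s + if (cr < 1.2) 0 else if (cr < 2) 1 else if (cr < 3.5) 2
    else if (cr < 5) 3 else 4
}

# brute-force AUC: count positive-negative pairs with half credit for ties
auc_bruteforce <- function(y, s) {
  pos <- s[y == 1]; neg <- s[y == 0]
  tot <- 0
  for (a in pos) for (b in neg) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# exhaustive threshold-sweep average precision
ap_bruteforce <- function(y, s) {
  th <- sort(unique(s), decreasing = TRUE)
  prec <- rec <- numeric(length(th))
  for (i in seq_along(th)) {
    sel <- s >= th[i]
    prec[i] <- sum(y[sel]) / sum(sel)
    rec[i] <- sum(y[sel]) / sum(y)
  }
  sum(diff(c(0, rec)) * prec)
}
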