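# Independent oracles, deliberately written with naive loops and no reuse
# of package internals.

# delete-one-PSU jackknife (JKn) SE of the weighted mean
jackknife_se_mean <- function(y, w, strata, psu) {
  est <- sum(w * y) / sum(w)
  v <- 0
  for (h in unique(strata)) {
    psus <- unique(psu[strata == h])
    nh <- length(psus)
    reps <- vapply(psus, function(j) {
      w2 <- w
      drop <- strata == h & psu == j
      w2[drop] <- 0
      infl <- strata == h & !drop
      w2[infl] <- w2[infl] * nh / (nh - 1)
      sum(w2 * y) / sum(w2)
    }, numeric(1))
    v <- v + (nh - 1) / nh * sum((reps - est)^2)
  }
  sqrt(v)
}

# brute-force per-subject per-group sums by explicit row scan
brute_group_sums <- function(items, group_codeset, subject_ids) {
  out <- stats::setNames(numeric(length(subject_ids)), subject_ids)
  for (r in seq_len(nrow(items))) {
    if (items$wweia_code[r] %in% group_codeset) {
      sid <- items$subject_id[r]
      if (sid %in% subject_ids) out[sid] <- out[sid] + items$grams[r]
    }
  }
  out
}
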