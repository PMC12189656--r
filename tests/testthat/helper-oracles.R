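# Independent brute-force oracles shared across test files.

# all-pairs Mann-Whitney counting oracle for the AUC
auc_bruteforce <- function(scores, labels, direction) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- if (direction == "higher_is_disease") {
    outer(pos, neg, ">")
  } else {
    outer(pos, neg, "<")
  }
  ties <- outer(pos, neg, "==")
  (sum(cmp) + 0.5 * sum(ties)) / (length(pos) * length(neg))
}

# exhaustive two-sided permutation p-value for the Mann-Whitney U test
mwu_perm_p <- function(x, y) {
  u_stat <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  all_v <- c(x, y)
  n <- length(x)
  idx <- utils::combn(length(all_v), n)
  u_obs <- u_stat(x, y)
  mu <- n * length(y) / 2
  us <- apply(idx, 2, function(i) u_stat(all_v[i], all_v[-i]))
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}
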