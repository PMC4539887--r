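# Shared fixture builders: everything is generated in code at test time.

# A ViewMatrix from an explicit matrix, ids auto-filled when missing.
toyView <- function(m, name = "toy") {
  if (is.null(rownames(m))) rownames(m) <- paste0("f", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("p", seq_len(ncol(m)))
  new("ViewMatrix", name = name, values = m)
}

# Two well-separated feature blocks driven by independent latent factors.
twoBlockView <- function(n_per_block = 5, n_patients = 60, seed = 1) {
  set.seed(seed)
  z1 <- rnorm(n_patients); z2 <- rnorm(n_patients)
  m <- rbind(
    t(replicate(n_per_block, 3 * z1 + rnorm(n_patients, sd = 0.3))),
    t(replicate(n_per_block, 3 * z2 + rnorm(n_patients, sd = 0.3))))
  toyView(m, "blocks")
}

# Labelled two-class patient data with one strongly informative view.
labelledToy <- function(n = 40, p = 12, effect = 3, seed = 1) {
  set.seed(seed)
  labels <- setNames(factor(rep(c("A", "B"), each = n / 2)),
                     sprintf("p%02d", seq_len(n)))
  m <- matrix(rnorm(p * n), p, n,
              dimnames = list(paste0("f", seq_len(p)), names(labels)))
  m[1:3, labels == "A"] <- m[1:3, labels == "A"] + effect
  list(view = toyView(m, "lab"), labels = labels)
}

# Memberships all carrying the same planted partition.
identicalViewMemberships <- function(partition, n_views = 3) {
  lapply(paste0("v", seq_len(n_views)),
         function(v) asMembership(partition, v))
}

# Independent brute-force hypergeometric tail: P(overlap >= a) for a cluster
# of size n drawn from N patients of whom K carry the majority class.
fisherOracle <- function(a, K, N, n) {
  j <- a:min(K, n)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# Write a small delimited matrix file and return its path.
writeDelim <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
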