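# Independent oracles and small fixture builders used across tests.

# Benjamini-Hochberg step-up, written independently of stats::p.adjust:
# sort, scale by m/i, enforce monotonicity from the largest rank down.
bh_stepup_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o] * m / seq_len(m)
  adj <- numeric(m)
  cur <- Inf
  for (i in m:1) {
    cur <- min(cur, ranked[i], 1)
    adj[i] <- cur
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# Hypergeometric upper tail P[X >= k] by explicit pmf summation on the
# log-binomial scale.
hyper_tail_oracle <- function(k, set_size, universe, query_size) {
  j <- k:min(set_size, query_size)
  if (length(j) == 0L || k > min(set_size, query_size)) return(0)
  sum(exp(lchoose(set_size, j) + lchoose(universe - set_size, query_size - j) -
            lchoose(universe, query_size)))
}

# A norm_matrix straight from given log-scale values (bypasses CPM).
as_norm <- function(values, feature_level = "gene") {
  structure(values, class = c("norm_matrix", class(matrix())),
            feature_level = feature_level)
}

rand_norm <- function(nf, ns, seed, mean = 5, sd = 1, prefix = "F",
                      samples = sprintf("s%03d", seq_len(ns))) {
  set.seed(seed)
  as_norm(matrix(rnorm(nf * ns, mean, sd), nrow = nf,
                 dimnames = list(sprintf("%s%04d", prefix, seq_len(nf)), samples)))
}

# Raw-sample fixture: returns the per-category raw sample matrix plus the
# atlas and group built from it, for summary-vs-raw equivalence checks.
raw_screen_fixture <- function(nf = 50, n_cat = 6, spc = 5, input_n = 4,
                               seed = 1) {
  set.seed(seed)
  feats <- sprintf("F%04d", seq_len(nf))
  cats <- sprintf("cat%02d", seq_len(n_cat))
  samples <- as.vector(vapply(cats, function(ct)
    sprintf("%s_s%d", ct, seq_len(spc)), character(spc)))
  mu <- matrix(rnorm(nf * n_cat, 5, 1), nrow = nf)
  bg <- mu[, rep(seq_len(n_cat), each = spc)] + rnorm(nf * n_cat * spc, 0, 0.7)
  dimnames(bg) <- list(feats, samples)
  ann <- data.frame(sample_id = samples, category = rep(cats, each = spc))
  inp <- matrix(rnorm(nf * input_n, rnorm(nf, 6, 1), 0.7),
                nrow = nf, dimnames = list(feats, sprintf("in_s%d", seq_len(input_n))))
  list(bg = bg, ann = ann, inp = inp,
       atlas = build_atlas(as_norm(bg), ann, "raw_fx"),
       group = summarize_group(as_norm(inp), "grp"))
}

# Write a GMT file from a named list of member vectors; returns the path.
write_gmt_file <- function(sets, path = tempfile(fileext = ".gmt")) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, "desc", sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  path
}

toy_gene_set <- function(name, members) gene_set(name, members)
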