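# Shared fixtures built in code.

# naive count-and-sum reimplementation of the entropy score, kept
# deliberately independent of the package's vectorized path
naive_entropy_score <- function(rows, base = 2) {
  m <- do.call(rbind, strsplit(toupper(rows), "", fixed = TRUE))
  hs <- numeric(ncol(m))
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    col <- col[!(col %in% c("-", ".", "X"))]
    if (!length(col)) next
    h <- 0
    for (a in unique(col)) {
      p <- sum(col == a) / length(col)
      h <- h - p * log(p, base = base)
    }
    hs[j] <- h
  }
  sum(hs) / ncol(m)
}

# a tiny fast simulation world for unit tests; ... overrides any default
tiny_config <- function(..., seed = 1) {
  sched <- data.frame(time_point = c("t1", "t2", "t3"),
                      log10_cfu = c(5.2, 0, 5.2),
                      stringsAsFactors = FALSE)
  args <- list(genes = list(gene_model("conA", 300, 0.9),
                            gene_model("conB", 300, 0.5),
                            gene_model("free", 300, 0.0)),
               n_clades = 3, founder_divergence_nt = 20,
               mu = 1e-4, generations_per_interval = 4,
               schedule = sched, effective_size_cap = 200,
               trough_effective_size = 32,
               sample_sizes = c(t1 = 10L, t3 = 10L),
               seed = seed)
  over <- list(...)
  for (k in names(over)) args[[k]] <- over[[k]]
  do.call(simulation_config, args)
}

random_protein_alignment <- function(n, L) {
  aas <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L")
  rows <- vapply(seq_len(n), function(i)
    paste(sample(aas, L, replace = TRUE), collapse = ""), "")
  stats::setNames(rows, paste0("s", seq_len(n)))
}
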