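#' Translate a coding sequence with the bacterial genetic code
#'
#' Translation uses genetic code table 11. Codons containing `N` become
#' `X`; a single trailing stop codon is trimmed; internal stops are emitted
#' as `*` (and warned about) so that pseudogenization shows up as entropy
#' rather than vanishing. With `init_codon = TRUE` the first codon follows
#' the table-11 alternative-initiation rule (e.g. GTG translates to M).
#'
#' @param cds nucleotide string (characters A, C, G, T, N), length a
#'   multiple of 3.
#' @param table genetic code id (only "11" is supported).
#' @param init_codon apply the first-codon start rule.
#' @param warn warn on internal stop codons.
#' @param id record name used in error messages.
#' @return amino-acid string; attribute `internal_stops` gives the count.
#' @export
translate_cds <- function(cds, table = "11", init_codon = TRUE, warn = TRUE,
                          id = "sequence") {
  stopifnot(is.character(cds), length(cds) == 1L)
  cds <- toupper(cds)
  if (nchar(cds) %% 3L != 0L)
    stop("CDS length of record '", id, "' (", nchar(cds),
         ") is not a multiple of 3")
  if (grepl("[^ACGTN]", cds))
    stop("record '", id, "' contains characters outside {A,C,G,T,N}")
  code <- Biostrings::getGeneticCode(as.character(table))
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(cds), genetic.code = code,
    if.fuzzy.codon = "X", no.init.codon = !init_codon))
  # trim one trailing stop
  if (nchar(aa) > 0L && substring(aa, nchar(aa), nchar(aa)) == "*")
    aa <- substring(aa, 1L, nchar(aa) - 1L)
  n_internal <- lengths(regmatches(aa, gregexpr("*", aa, fixed = TRUE)))
  if (n_internal > 0L && warn)
    warning("record '", id, "' contains ", n_internal,
            " internal stop codon(s)", call. = FALSE)
  attr(aa, "internal_stops") <- n_internal
  aa
}

#' Shannon entropy of one alignment column
#'
#' H = -sum_a p_a log(p_a) over the residues observed in the column, with
#' p_a the count of residue a divided by the number of informative (non-gap,
#' non-X) residues. Gaps (`-`, `.`) and `X` are excluded from the counts; a
#' column with no informative residue scores 0. Stop (`*`) participates as
#' a 21st symbol.
#'
#' @param column character vector of single residues (or one string, split
#'   into residues).
#' @param base logarithm base: 2 for bits (default) or `exp(1)` for nats.
#' @return entropy, >= 0; exactly 0 for fully conserved columns.
#' @export
column_entropy <- function(column, base = 2) {
  if (length(column) == 1L && nchar(column) > 1L)
    column <- strsplit(column, "", fixed = TRUE)[[1L]]
  if (length(column) == 0L) stop("empty column")
  res <- toupper(column)
  res <- res[!res %in% c("-", ".", "X")]
  if (length(res) == 0L) return(0)
  p <- as.vector(table(res)) / length(res)
  h <- -sum(p * log(p)) / log(base)
  max(h, 0)
}

#' Translate a whole gene set at once
#'
#' Vectorized companion to [translate_cds()] (one Biostrings call instead
#' of one dispatch per record). Terminal stop codons are trimmed only when
#' every record ends in one, so a mutant stop in the last codon stays
#' visible as a `*` variant column in the alignment.
#'
#' @param seqs named character vector of CDS (ids -> sequence).
#' @inheritParams translate_cds
#' @return named character vector of amino-acid strings; attribute
#'   `internal_stops` counts internal stop codons across all records.
#' @export
translate_cds_set <- function(seqs, table = "11", init_codon = TRUE) {
  stopifnot(is.character(seqs), length(seqs) >= 1L)
  seqs <- toupper(seqs)
  ids <- names(seqs) %||% paste0("seq", seq_along(seqs))
  bad_len <- nchar(seqs) %% 3L != 0L
  if (any(bad_len))
    stop("CDS length not a multiple of 3 for record(s): ",
         paste(ids[bad_len], collapse = ", "))
  bad_chr <- grepl("[^ACGTN]", seqs)
  if (any(bad_chr))
    stop("characters outside {A,C,G,T,N} in record(s): ",
         paste(ids[bad_chr], collapse = ", "))
  code <- Biostrings::getGeneticCode(as.character(table))
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAStringSet(seqs), genetic.code = code,
    if.fuzzy.codon = "X", no.init.codon = !init_codon))
  # trim terminal stops only when the whole set carries them, so that a
  # mutant stop in the last codon stays visible as a '*' variant column
  trailing <- substring(aa, nchar(aa), nchar(aa)) == "*"
  if (all(trailing))
    aa <- substring(aa, 1L, nchar(aa) - 1L)
  n_internal <- vapply(gregexpr("*", aa, fixed = TRUE),
                       function(m) sum(m > 0L), 0L)
  names(aa) <- ids
  attr(aa, "internal_stops") <- sum(n_internal)
  aa
}

as_alignment_matrix <- function(rows) {
  if (is.matrix(rows)) return(rows)
  stopifnot(is.character(rows), length(rows) >= 1L)
  L <- unique(nchar(rows))
  if (length(L) != 1L)
    stop("alignment rows have unequal lengths: ",
         paste(sort(unique(nchar(rows))), collapse = ", "))
  ids <- names(rows) %||% paste0("seq", seq_along(rows))
  if (anyDuplicated(ids)) stop("duplicate sequence ids in alignment")
  m <- matrix(unlist(strsplit(toupper(rows), "", fixed = TRUE), use.names = FALSE),
              nrow = length(rows), byrow = TRUE)
  rownames(m) <- ids
  m
}

#' Length-standardized entropy score of a gene's protein alignment
#'
#' Per-column Shannon entropies are summed and divided by the alignment
#' length L, yielding one conservation value per gene (0 = perfectly
#' conserved). The score is invariant to row order and to duplicating the
#' whole row set.
#'
#' @param alignment named character vector of equal-length amino-acid
#'   strings (ids -> rows), or a character matrix of residues.
#' @param gene gene name carried into the profile.
#' @param base entropy log base (2 = bits).
#' @return object of class `entropy_profile` with fields `gene`,
#'   `per_column`, `score`, `n_sequences`, `L`, `log_base`.
#' @export
gene_entropy_score <- function(alignment, gene = "gene", base = 2) {
  m <- as_alignment_matrix(alignment)
  if (nrow(m) < 2L)
    stop("entropy requires >= 2 sequences (gene '", gene, "')")
  # one cross-tabulation per gene; agrees with column_entropy per column
  L <- ncol(m)
  keep <- !(m %in% c("-", ".", "X"))
  cols <- factor(rep(seq_len(L), each = nrow(m))[keep], levels = seq_len(L))
  counts <- table(cols, m[keep])
  tot <- rowSums(counts)
  p <- counts / pmax(tot, 1L)
  logp <- ifelse(p > 0, log(p), 0)
  per_column <- as.vector(-rowSums(p * logp)) / log(base)
  per_column[tot == 0L] <- 0
  per_column <- pmax(per_column, 0)
  structure(list(gene = gene, per_column = per_column,
                 score = sum(per_column) / ncol(m),
                 n_sequences = nrow(m), L = ncol(m),
                 log_base = base),
            class = "entropy_profile")
}

#' @export
print.entropy_profile <- function(x, ...) {
  cat(sprintf("entropy profile: %s  (n = %d, L = %d, base %s)\n  score = %.6g\n",
              x$gene, x$n_sequences, x$L,
              if (isTRUE(all.equal(x$log_base, 2))) "2 (bits)" else
                format(x$log_base), x$score))
  invisible(x)
}

#' Compare entropy scores between two gene groups
#'
#' Tests whether target genes (e.g. the TDA cluster) carry more diversity
#' than reference housekeeping genes. The t-statistic (Welch by default,
#' Student optional) is always reported when both groups have >= 2 values;
#' permutation methods additionally compute the exact (all C(n1+n2, n1)
#' relabelings of the mean difference, when that count is at most 200000)
#' or Monte-Carlo permutation p-values.
#'
#' @param target_scores,reference_scores numeric score vectors.
#' @param alternative "greater" (target > reference) or "two_sided".
#' @param method "welch", "student", "permutation_exact" or
#'   "permutation_mc".
#' @param n_permutations Monte-Carlo draws for "permutation_mc".
#' @param seed RNG seed for Monte-Carlo permutation.
#' @return object of class `group_comparison` with t-statistic, df,
#'   two-sided and one-sided-greater p-values, and permutation p-values
#'   when requested (`p_permutation` follows `alternative`).
#' @export
compare_groups <- function(target_scores, reference_scores,
                           alternative = c("greater", "two_sided"),
                           method = c("welch", "student",
                                      "permutation_exact", "permutation_mc"),
                           n_permutations = 10000, seed = 1) {
  alternative <- match.arg(alternative)
  method <- match.arg(method)
  x <- as.numeric(target_scores); y <- as.numeric(reference_scores)
  if (grepl("^permutation", method)) {
    if (length(x) < 1L || length(y) < 1L)
      stop("permutation test needs >= 1 value per group")
  } else if (length(x) < 2L || length(y) < 2L) {
    stop("t-test needs >= 2 values per group")
  }
  out <- list(target_scores = x, reference_scores = y, method = method,
              alternative = alternative, degenerate = FALSE)

  # t branch (always reported when group sizes permit)
  if (length(x) >= 2L && length(y) >= 2L) {
    vx <- stats::var(x); vy <- stats::var(y)
    if (vx == 0 && vy == 0 && mean(x) == mean(y)) {
      out$degenerate <- TRUE
      out$t_statistic <- NA_real_; out$df <- NA_real_
      out$p_two_sided <- 1; out$p_one_sided_greater <- 1
    } else if (method == "student") {
      sp2 <- ((length(x) - 1) * vx + (length(y) - 1) * vy) /
        (length(x) + length(y) - 2)
      se <- sqrt(sp2 * (1 / length(x) + 1 / length(y)))
      out$t_statistic <- (mean(x) - mean(y)) / se
      out$df <- length(x) + length(y) - 2
      out$p_two_sided <- 2 * stats::pt(-abs(out$t_statistic), out$df)
      out$p_one_sided_greater <- stats::pt(out$t_statistic, out$df,
                                           lower.tail = FALSE)
    } else {
      sex <- vx / length(x); sey <- vy / length(y)
      out$t_statistic <- (mean(x) - mean(y)) / sqrt(sex + sey)
      out$df <- (sex + sey)^2 /
        (sex^2 / (length(x) - 1) + sey^2 / (length(y) - 1))
      out$p_two_sided <- 2 * stats::pt(-abs(out$t_statistic), out$df)
      out$p_one_sided_greater <- stats::pt(out$t_statistic, out$df,
                                           lower.tail = FALSE)
    }
  } else {
    out$t_statistic <- NA_real_; out$df <- NA_real_
    out$p_two_sided <- NA_real_; out$p_one_sided_greater <- NA_real_
  }

  if (grepl("^permutation", method)) {
    pooled <- c(x, y)
    n1 <- length(x); n <- length(pooled)
    obs <- mean(x) - mean(y)
    eps <- 1e-12
    n_part <- choose(n, n1)
    if (method == "permutation_exact" && n_part <= 200000) {
      idx <- utils::combn(n, n1)
      diffs <- apply(idx, 2L, function(ix)
        mean(pooled[ix]) - mean(pooled[-ix]))
      out$n_permutations_or_exact <- list(exact = TRUE, n = n_part)
    } else {
      if (method == "permutation_exact")
        pp_log("C(", n, ",", n1, ") = ", n_part,
               " > 200000; falling back to Monte-Carlo permutation")
      diffs <- with_seed(seed, vapply(seq_len(n_permutations), function(b) {
        ix <- sample.int(n, n1)
        mean(pooled[ix]) - mean(pooled[-ix])
      }, 0.0))
      # observed labeling counts as one draw
      diffs <- c(obs, diffs)
      out$n_permutations_or_exact <- list(exact = FALSE,
                                          n = n_permutations + 1L)
    }
    out$p_perm_greater <- mean(diffs >= obs - eps)
    out$p_perm_two_sided <- mean(abs(diffs) >= abs(obs) - eps)
    out$p_permutation <- if (alternative == "greater") out$p_perm_greater
                         else out$p_perm_two_sided
  }
  structure(out, class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("group comparison (%s, alternative = %s)\n", x$method,
              x$alternative))
  cat(sprintf("  n = %d vs %d; mean diff = %.4g\n", length(x$target_scores),
              length(x$reference_scores),
              mean(x$target_scores) - mean(x$reference_scores)))
  if (!is.na(x$t_statistic))
    cat(sprintf("  t = %.4g (df = %.3g), two-sided p = %.4g, one-sided p = %.4g\n",
                x$t_statistic, x$df, x$p_two_sided, x$p_one_sided_greater))
  if (!is.null(x$p_permutation))
    cat(sprintf("  permutation p (%s) = %.4g [%s, n = %d]\n", x$alternative,
                x$p_permutation,
                if (x$n_permutations_or_exact$exact) "exact" else "Monte-Carlo",
                x$n_permutations_or_exact$n))
  if (x$degenerate) cat("  note: zero variance in both groups, p set to 1\n")
  invisible(x)
}

#' Gene-conservation report with group comparison
#'
#' Scores every gene's alignment and tests target against reference genes.
#' CDS inputs are translated with the bacterial code first; pre-aligned
#' protein inputs are used as-is (the package does not align).
#'
#' @param sequences named list: gene -> named character vector of sequences
#'   (ids -> CDS or aligned protein rows of equal length).
#' @param groups named character vector: gene -> "target", "reference" or
#'   "other"; every gene in `sequences` must appear.
#' @param type "cds" (translate first) or "protein".
#' @param base entropy log base.
#' @param test method passed to [compare_groups()].
#' @param seed seed for Monte-Carlo permutation.
#' @return object of class `conservation_report`: `table` (gene, group,
#'   n_sequences, L, score; deterministic row order: group then gene),
#'   `comparison`, `profiles`, `log_base`.
#' @export
conservation_report <- function(sequences, groups, type = c("cds", "protein"),
                                base = 2, test = "permutation_exact",
                                seed = 1) {
  type <- match.arg(type)
  stopifnot(is.list(sequences), length(sequences) >= 1L)
  gene_names <- names(sequences)
  if (is.null(gene_names) || any(!nzchar(gene_names)))
    stop("'sequences' must be a named list of per-gene sequence sets")
  missing_grp <- setdiff(gene_names, names(groups))
  if (length(missing_grp))
    stop("gene(s) missing from group map: ", paste(missing_grp, collapse = ", "))
  bad_grp <- setdiff(unique(groups), c("target", "reference", "other"))
  if (length(bad_grp))
    stop("group map values must be target/reference/other, got: ",
         paste(bad_grp, collapse = ", "))

  profiles <- list()
  n_stops <- 0L
  for (g in gene_names) {
    seqs <- sequences[[g]]
    if (length(seqs) < 2L) {
      warning("gene '", g, "' has fewer than 2 sequences; excluded",
              call. = FALSE)
      next
    }
    if (type == "cds") {
      aa <- translate_cds_set(seqs)
      n_stops <- n_stops + attr(aa, "internal_stops")
      seqs <- aa
    }
    profiles[[g]] <- gene_entropy_score(seqs, gene = g, base = base)
  }
  if (n_stops > 0L)
    pp_log(n_stops, " internal stop codon(s) across translated records ",
           "(kept as '*', a 21st symbol)")
  if (!length(profiles)) stop("no gene with >= 2 sequences")

  tab <- data.frame(
    gene = names(profiles),
    group = unname(groups[names(profiles)]),
    n_sequences = vapply(profiles, `[[`, 0L, "n_sequences"),
    L = vapply(profiles, `[[`, 0L, "L"),
    score = vapply(profiles, `[[`, 0.0, "score"),
    stringsAsFactors = FALSE
  )
  tab <- tab[order(factor(tab$group, levels = c("target", "reference", "other")),
                   tab$gene), , drop = FALSE]
  rownames(tab) <- NULL

  comparison <- NULL
  tgt <- tab$score[tab$group == "target"]
  ref <- tab$score[tab$group == "reference"]
  if (length(tgt) >= 1L && length(ref) >= 1L)
    comparison <- compare_groups(tgt, ref, alternative = "greater",
                                 method = test, seed = seed)
  structure(list(table = tab, comparison = comparison, profiles = profiles,
                 log_base = base),
            class = "conservation_report")
}

#' Write a conservation report as TSV and JSON
#'
#' @param report a [conservation_report()].
#' @param tsv,json output paths (either may be NULL to skip).
#' @return invisibly, the report.
#' @export
write_conservation_report <- function(report, tsv = NULL, json = NULL) {
  stopifnot(inherits(report, "conservation_report"))
  if (!is.null(tsv))
    utils::write.table(report$table, tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(json)) {
    payload <- list(
      log_base = report$log_base,
      table = report$table,
      per_column = lapply(report$profiles, `[[`, "per_column"),
      comparison = if (!is.null(report$comparison))
        unclass(report$comparison)[c("t_statistic", "df", "p_two_sided",
                                     "p_one_sided_greater", "p_permutation",
                                     "method", "alternative", "degenerate")]
    )
    jsonlite::write_json(payload, json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(report)
}
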