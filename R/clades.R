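#' Exact pairwise identity matrix for equal-length sequences
#'
#' Synthetic stand-in for whole-genome ANI: value(i, j) is the fraction of
#' positions at which the two sequences carry the same base. Exact and
#' deterministic; inputs must be gap-free and of equal length (synthetic
#' concatenates never need alignment).
#'
#' @param sequences named character vector of equal-length nucleotide
#'   strings (ids -> sequence).
#' @return symmetric numeric matrix with unit diagonal and ids as dimnames,
#'   class `identity_matrix`.
#' @export
pairwise_identity <- function(sequences) {
  stopifnot(is.character(sequences), length(sequences) >= 2L)
  L <- unique(nchar(sequences))
  if (length(L) != 1L)
    stop("sequences have unequal lengths: ",
         paste(sort(unique(nchar(sequences))), collapse = ", "))
  ids <- names(sequences) %||% paste0("seq", seq_along(sequences))
  if (anyDuplicated(ids)) stop("duplicate sequence ids")
  chars <- strsplit(toupper(sequences), "", fixed = TRUE)
  if (any(vapply(chars, function(x) any(x %in% c("-", ".")), NA)))
    stop("gap characters are not allowed in identity computation")
  m <- matrix(unlist(chars, use.names = FALSE), nrow = length(sequences),
              byrow = TRUE)
  alphabet <- sort(unique(as.vector(m)))
  matches <- matrix(0, nrow(m), nrow(m))
  for (a in alphabet) {
    ind <- (m == a) * 1
    matches <- matches + tcrossprod(ind)
  }
  out <- matches / L
  diag(out) <- 1
  dimnames(out) <- list(ids, ids)
  class(out) <- c("identity_matrix", class(out))
  out
}

validate_identity_matrix <- function(m, tol = 1e-12) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) stop("identity matrix must be square")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("identity matrix must carry isolate labels")
  if (!identical(rownames(m), colnames(m)))
    stop("row and column labels differ")
  if (max(abs(m - t(m))) > tol) stop("identity matrix is not symmetric")
  if (max(abs(diag(m) - 1)) > tol) stop("identity matrix diagonal must be 1")
  if (min(m) < -tol || max(m) > 1 + tol) stop("identity values must lie in [0, 1]")
  invisible(m)
}

#' Read a labeled square identity/ANI matrix
#'
#' Accepts TSV or CSV with isolate labels as header and first column.
#' Percent-scale matrices (values > 1.5) are rescaled to \[0, 1\] with a
#' notice; asymmetry within `tol` is averaged out with a warning, beyond it
#' is an error.
#'
#' @param path file path.
#' @param tol symmetry tolerance.
#' @return an `identity_matrix`.
#' @export
read_ani_matrix <- function(path, tol = 1e-6) {
  if (!file.exists(path)) stop("no such file: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, sep = sep, header = TRUE, row.names = 1L,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m)) stop("non-numeric entries in matrix file: ", path)
  if (nrow(m) != ncol(m))
    stop("matrix in ", path, " is not square (", nrow(m), " x ", ncol(m), ")")
  if (is.null(rownames(m)) || !identical(rownames(m), colnames(m)))
    stop("matrix in ", path, " must carry matching row/column labels")
  if (max(m) > 1.5) {
    pp_log("values look percent-scaled (max = ", format(max(m)),
           "); rescaling to [0, 1]")
    m <- m / 100
  }
  asym <- max(abs(m - t(m)))
  if (asym > tol)
    stop("matrix asymmetric beyond tolerance (max |m - t(m)| = ",
         format(asym), ")")
  if (asym > 0) {
    warning("matrix slightly asymmetric (max ", format(asym),
            "); symmetrized by averaging", call. = FALSE)
    m <- (m + t(m)) / 2
  }
  diag(m) <- 1
  validate_identity_matrix(m, tol = 1e-8)
  class(m) <- c("identity_matrix", class(m))
  m
}

#' Assign isolates to clades by hierarchical clustering
#'
#' Agglomerative clustering on distance 1 - identity; flat clades are cut
#' at distance 1 - `cut_identity`. A cut above the largest off-diagonal
#' identity yields one clade per isolate (allowed, not an error). Clades
#' are numbered by first appearance in input order.
#'
#' @param matrix an `identity_matrix`.
#' @param cut_identity identity threshold in (0, 1]; isolates merged at or
#'   above it share a clade.
#' @param linkage linkage method for [stats::hclust()] (default "average").
#' @return object of class `clade_assignment`: `ids`, `clade_of` (named
#'   integer), `n_clades`, `linkage`, `cut_identity`, `hclust`.
#' @export
cluster_clades <- function(matrix, cut_identity, linkage = "average") {
  validate_identity_matrix(matrix, tol = 1e-8)
  if (!is.numeric(cut_identity) || cut_identity <= 0 || cut_identity > 1)
    stop("cut_identity must lie in (0, 1]")
  d <- stats::as.dist(1 - matrix)
  hc <- stats::hclust(d, method = linkage)
  raw <- stats::cutree(hc, h = 1 - cut_identity)
  # renumber by first appearance in input order
  first_seen <- unique(raw)
  clade_of <- match(raw, first_seen)
  names(clade_of) <- rownames(matrix)
  structure(list(ids = rownames(matrix), clade_of = clade_of,
                 n_clades = length(first_seen), linkage = linkage,
                 cut_identity = cut_identity, hclust = hc),
            class = "clade_assignment")
}

#' Dendrogram of a clade assignment in Newick format
#'
#' Branch lengths are the merge distances (1 - identity) of the underlying
#' hierarchical clustering.
#'
#' @param assignment a [cluster_clades()] result.
#' @param path optional file to write; otherwise the Newick string is
#'   returned.
#' @return the Newick string, invisibly when written to file.
#' @export
clade_newick <- function(assignment, path = NULL) {
  stopifnot(inherits(assignment, "clade_assignment"))
  phy <- ape::as.phylo(assignment$hclust)
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}

#' Minimum identity and species-threshold check
#'
#' @param matrix an `identity_matrix`.
#' @param species_threshold conventional species delineation (default 0.95).
#' @return list with `min_identity` (minimum off-diagonal value) and
#'   `single_species` (TRUE when min_identity >= threshold).
#' @export
species_check <- function(matrix, species_threshold = 0.95) {
  validate_identity_matrix(matrix, tol = 1e-8)
  off <- matrix[row(matrix) != col(matrix)]
  min_id <- if (length(off)) min(off) else 1
  list(min_identity = min_id,
       single_species = min_id >= species_threshold,
       species_threshold = species_threshold)
}

#' Clade relative-abundance timeline
#'
#' Per sampled time point, the fraction of isolates belonging to each
#' clade; clades absent at a time point are reported as 0. Time points with
#' no isolates are omitted with a notice. A persistence summary lists the
#' first and last time point at which each clade was seen.
#'
#' @param assignment a [cluster_clades()] result, or a named vector of
#'   clade labels (isolate id -> clade).
#' @param metadata data.frame with `isolate_id` and `time_point` columns;
#'   time points are taken in order of first appearance unless
#'   `time_point` is a factor.
#' @return object of class `clade_timeline`: `fractions` (time point x
#'   clade matrix), `counts`, `n_isolates`, `persistence`.
#' @export
clade_relative_abundance <- function(assignment, metadata) {
  clade_of <- if (inherits(assignment, "clade_assignment"))
    assignment$clade_of else assignment
  stopifnot(!is.null(names(clade_of)))
  stopifnot(is.data.frame(metadata),
            all(c("isolate_id", "time_point") %in% names(metadata)))
  unassigned <- setdiff(metadata$isolate_id, names(clade_of))
  if (length(unassigned))
    stop("isolate(s) without clade assignment: ",
         paste(utils::head(unassigned, 5L), collapse = ", "))
  tp_levels <- if (is.factor(metadata$time_point)) levels(metadata$time_point)
               else unique(metadata$time_point)
  clades <- sort(unique(clade_of[metadata$isolate_id]))
  counts <- matrix(0L, nrow = length(tp_levels), ncol = length(clades),
                   dimnames = list(tp_levels, as.character(clades)))
  for (i in seq_len(nrow(metadata))) {
    tp <- as.character(metadata$time_point[i])
    cl <- as.character(clade_of[[metadata$isolate_id[i]]])
    counts[tp, cl] <- counts[tp, cl] + 1L
  }
  n_iso <- rowSums(counts)
  empty <- n_iso == 0L
  if (any(empty)) {
    pp_log("omitting ", sum(empty), " time point(s) with no isolates: ",
           paste(tp_levels[empty], collapse = ", "))
    counts <- counts[!empty, , drop = FALSE]
    n_iso <- n_iso[!empty]
  }
  if (!nrow(counts)) stop("no time point with isolates")
  fractions <- sweep(counts, 1L, n_iso, "/")
  persistence <- do.call(rbind, lapply(colnames(counts), function(cl) {
    seen <- which(counts[, cl] > 0L)
    data.frame(clade = as.integer(cl),
               first = rownames(counts)[min(seen)],
               last = rownames(counts)[max(seen)],
               n_time_points = length(seen),
               n_isolates = sum(counts[, cl]),
               stringsAsFactors = FALSE)
  }))
  structure(list(fractions = fractions, counts = counts,
                 n_isolates = n_iso, persistence = persistence),
            class = "clade_timeline")
}

#' @export
print.clade_timeline <- function(x, ...) {
  cat("clade timeline over", nrow(x$fractions), "time points,",
      ncol(x$fractions), "clades\n")
  print(round(x$fractions, 3))
  invisible(x)
}
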