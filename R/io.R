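#' Read a FASTA file
#'
#' Record ids are the first whitespace-delimited token of each header, the
#' remainder is kept as the description. Sequences are upper-cased (with a
#' log notice when the input was mixed-case). Duplicate ids and empty
#' files are errors.
#'
#' @param path file path.
#' @return named character vector (id -> sequence) with attribute
#'   `descriptions`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids))
    stop("duplicate record id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- as.character(set)
  if (any(seqs != toupper(seqs))) {
    pp_log("mixed-case sequence(s) in ", basename(path), "; upper-casing")
    seqs <- toupper(seqs)
  }
  if (any(!nzchar(seqs))) stop("empty record(s) in ", path)
  names(seqs) <- ids
  attr(seqs, "descriptions") <- stats::setNames(desc, ids)
  seqs
}

#' Write sequences as FASTA
#'
#' @param x named character vector (id -> sequence).
#' @param path output path.
#' @param descriptions optional named character vector appended to headers.
#' @param width line-wrapping width (default 60 columns).
#' @return invisibly, `path`.
#' @export
write_fasta <- function(x, path, descriptions = NULL, width = 60) {
  stopifnot(is.character(x), length(x) >= 1L, !is.null(names(x)))
  if (anyDuplicated(names(x))) stop("duplicate record ids")
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(x)) {
    hdr <- id
    if (!is.null(descriptions) && !is.na(descriptions[id]) &&
        nzchar(descriptions[id] %||% ""))
      hdr <- paste(id, descriptions[[id]])
    writeLines(paste0(">", hdr), con)
    s <- x[[id]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read every per-gene FASTA in a directory
#'
#' @param dir directory containing `<gene>.fasta` / `<gene>.fa` files.
#' @return named list: gene (file stem) -> named character vector.
#' @export
read_gene_fasta_dir <- function(dir) {
  if (!dir.exists(dir)) stop("no such directory: ", dir)
  files <- sort(list.files(dir, pattern = "\\.(fa|fasta|faa|fna)$",
                           full.names = TRUE))
  if (!length(files)) stop("no FASTA files found in ", dir)
  stats::setNames(lapply(files, read_fasta),
                  tools::file_path_sans_ext(basename(files)))
}

#' Read an isolate metadata CSV
#'
#' Schema: `isolate_id,time_point,source,clade` (clade optional).
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_isolate_metadata <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("isolate_id", "time_point", "source")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("metadata ", path, " lacks column(s): ", paste(miss, collapse = ", "))
  df
}

#' Write / read censored abundance series as CSV
#'
#' Schema: `compartment,time_point,replicate,log10_cfu,censored`.
#'
#' @param series a [censored_series()] or list of them.
#' @param path file path.
#' @return `write_abundance_csv`: invisibly, the path.
#' @export
write_abundance_csv <- function(series, path) {
  if (inherits(series, "censored_series")) series <- list(series)
  df <- do.call(rbind, lapply(series, function(s) {
    data.frame(compartment = s$compartment,
               time_point = as.character(s$time_point),
               replicate = s$replicate, log10_cfu = s$log10_cfu,
               censored = s$censored, stringsAsFactors = FALSE)
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_abundance_csv
#' @param lod limit of detection attached to the series read back.
#' @return `read_abundance_csv`: named list of [censored_series()], one per
#'   compartment (a bare series if only one compartment is present).
#' @export
read_abundance_csv <- function(path, lod = 1.0) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("compartment", "time_point", "replicate", "log10_cfu", "censored")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("abundance ", path, " lacks column(s): ", paste(miss, collapse = ", "))
  out <- lapply(split(df, df$compartment), function(sub) {
    censored_series(time_point = sub$time_point, log10_cfu = sub$log10_cfu,
                    replicate = sub$replicate,
                    compartment = sub$compartment[1L],
                    censored = as.logical(sub$censored), lod = lod)
  })
  if (length(out) == 1L) out[[1L]] else out
}

#' Parse the sampling/isolate inventory table
#'
#' Reads the packaged 20-event sampling inventory (or a user table with the
#' same schema): per sampling, physico-chemical measurements and the
#' numbers of isolates obtained and whole-genome sequenced. "ND" denotes a
#' missing measurement; the two samplings where only DNA/RNA material was
#' collected have missing counts and contribute 0 to totals. The printed
#' "Total" row is authoritative for the totals; the row-wise sums are also
#' returned, and any discrepancy between the two is reported with a
#' message rather than silently reconciled.
#'
#' @param path CSV path; `NULL` uses the packaged fixture.
#' @return list with `records` (data.frame, one row per sampling),
#'   `totals` (printed totals: obtained, sequenced) and `computed_totals`
#'   (row-wise sums).
#' @export
parse_sampling_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "sampling_table.csv", package = "phaeopop",
                        mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("label", "temperature_c", "salinity_ppt", "ph", "oxygen_mg_l",
            "isolates_obtained", "isolates_sequenced")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("sampling table lacks column(s): ", paste(miss, collapse = ", "))
  if (!nrow(df)) stop("empty sampling table: ", path)
  num <- function(x, label, col) {
    x <- trimws(x)
    if (x %in% c("ND", "NA", "")) return(NA_real_)
    v <- suppressWarnings(as.numeric(x))
    if (is.na(v))
      stop("malformed numeric cell '", x, "' in column ", col,
           " of row '", label, "'")
    v
  }
  is_total <- df$label == "Total"
  printed <- NULL
  if (any(is_total)) {
    tr <- df[is_total, ][1L, ]
    printed <- c(obtained = num(tr$isolates_obtained, "Total",
                                "isolates_obtained"),
                 sequenced = num(tr$isolates_sequenced, "Total",
                                 "isolates_sequenced"))
    df <- df[!is_total, , drop = FALSE]
  }
  if (!nrow(df)) stop("sampling table has no data rows: ", path)
  records <- do.call(rbind, lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    rec <- data.frame(
      label = r$label, ordinal = i,
      temperature_c = num(r$temperature_c, r$label, "temperature_c"),
      salinity_ppt = num(r$salinity_ppt, r$label, "salinity_ppt"),
      ph = num(r$ph, r$label, "ph"),
      oxygen_mg_l = num(r$oxygen_mg_l, r$label, "oxygen_mg_l"),
      isolates_obtained = num(r$isolates_obtained, r$label,
                              "isolates_obtained"),
      isolates_sequenced = num(r$isolates_sequenced, r$label,
                               "isolates_sequenced"),
      stringsAsFactors = FALSE)
    both <- !is.na(rec$isolates_obtained) && !is.na(rec$isolates_sequenced)
    if (both && rec$isolates_sequenced > rec$isolates_obtained)
      stop("row '", r$label, "': sequenced > obtained")
    rec
  }))
  computed <- c(obtained = sum(records$isolates_obtained, na.rm = TRUE),
                sequenced = sum(records$isolates_sequenced, na.rm = TRUE))
  if (is.null(printed)) printed <- computed
  if (any(printed != computed))
    pp_log("printed totals (", printed[["obtained"]], ", ",
           printed[["sequenced"]], ") differ from row sums (",
           computed[["obtained"]], ", ", computed[["sequenced"]],
           "); printed totals are reported as authoritative")
  list(records = records, totals = printed, computed_totals = computed)
}
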