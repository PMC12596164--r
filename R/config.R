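# Run configuration: JSON via jsonlite, or a small YAML subset parsed
# in-package (no YAML parser is available as a dependency). The subset
# covers what the documented config schema needs: nested maps by 2-space
# indentation, scalars (numbers, booleans, quoted/bare strings), inline
# lists [a, b, c] and block lists ("- item").

yaml_scalar <- function(x) {
  x <- trimws(x)
  if (x == "" || x == "~" || x == "null") return(NULL)
  if (grepl("^\\[.*\\]$", x)) {
    inner <- trimws(substr(x, 2L, nchar(x) - 1L))
    if (inner == "") return(list())
    parts <- trimws(strsplit(inner, ",", fixed = TRUE)[[1L]])
    vals <- lapply(parts, yaml_scalar)
    return(simplify2array(vals))
  }
  if (grepl('^".*"$', x) || grepl("^'.*'$", x))
    return(substr(x, 2L, nchar(x) - 1L))
  if (x %in% c("true", "True", "TRUE", "yes")) return(TRUE)
  if (x %in% c("false", "False", "FALSE", "no")) return(FALSE)
  num <- suppressWarnings(as.numeric(x))
  if (!is.na(num)) return(num)
  x
}

parse_yaml_lite <- function(lines) {
  if (length(lines) == 1L && grepl("\n", lines))
    lines <- strsplit(lines, "\n", fixed = TRUE)[[1L]]
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  indents <- nchar(sub("\\S.*$", "", lines))
  parse_block <- function(from, to, indent) {
    out <- list()
    i <- from
    while (i <= to) {
      line <- lines[i]
      if (indents[i] != indent)
        stop("YAML parse error near line: ", trimws(line))
      body <- trimws(line)
      if (startsWith(body, "- ")) {
        # block list at this indent
        items <- list()
        while (i <= to && indents[i] == indent &&
               startsWith(trimws(lines[i]), "- ")) {
          items[[length(items) + 1L]] <- yaml_scalar(sub("^- ", "",
                                                         trimws(lines[i])))
          i <- i + 1L
        }
        return(simplify2array(items))
      }
      m <- regmatches(body, regexec("^([^:]+):\\s*(.*)$", body))[[1L]]
      if (length(m) != 3L) stop("YAML parse error near line: ", body)
      key <- trimws(m[2L]); rest <- m[3L]
      if (nzchar(trimws(rest))) {
        out[[key]] <- yaml_scalar(rest)
        i <- i + 1L
      } else {
        j <- i + 1L
        while (j <= to && indents[j] > indent) j <- j + 1L
        if (j == i + 1L) { out[[key]] <- NULL; i <- i + 1L; next }
        out[[key]] <- parse_block(i + 1L, j - 1L, indents[i + 1L])
        i <- j
      }
    }
    out
  }
  if (!length(lines)) return(list())
  parse_block(1L, length(lines), indents[1L])
}

PP_CONFIG_KEYS <- c("seed", "log_level", "paths", "simulation", "entropy",
                    "clades", "abundance")

#' Read a run configuration (JSON or YAML subset)
#'
#' Top-level keys are restricted to `seed`, `log_level`, `paths`, and the
#' per-module parameter blocks `simulation`, `entropy`, `clades`,
#' `abundance`; unknown keys are rejected. The effective configuration is
#' echoed to the log.
#'
#' @param path `.json`, `.yaml` or `.yml` file.
#' @return nested list of configuration values.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    parse_yaml_lite(readLines(path, warn = FALSE))
  }
  unknown <- setdiff(names(cfg), PP_CONFIG_KEYS)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         " (allowed: ", paste(PP_CONFIG_KEYS, collapse = ", "), ")")
  pp_log("effective config: ",
         jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA))
  cfg
}

# build a simulation_config from a config block (all fields optional)
config_to_simulation <- function(block, seed = NULL) {
  block <- block %||% list()
  args <- list()
  if (!is.null(block$genes)) {
    args$genes <- lapply(seq_along(block$genes$name), function(i)
      gene_model(block$genes$name[i], block$genes$cds_length_nt[i],
                 block$genes$constrained_fraction[i]))
  }
  for (k in c("n_clades", "founder_divergence_nt", "mu",
              "generations_per_interval", "effective_size_cap",
              "trough_effective_size", "lod", "seawater_fraction",
              "allow_extinction"))
    if (!is.null(block[[k]])) args[[k]] <- block[[k]]
  if (!is.null(block$years) || !is.null(block$peak_log10) ||
      !is.null(block$trough_log10)) {
    args$schedule <- default_schedule(
      years = block$years %||% 12,
      peak_log10 = block$peak_log10 %||% 5.2,
      trough_log10 = block$trough_log10 %||% 0)
  }
  if (!is.null(block$sample_sizes))
    args$sample_sizes <- unlist(block$sample_sizes)
  if (!is.null(seed)) args$seed <- seed
  else if (!is.null(block$seed)) args$seed <- block$seed
  do.call(simulation_config, args)
}
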