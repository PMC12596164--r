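PP_BASES <- c("A", "C", "G", "T")
PP_STOPS <- c("TAA", "TAG", "TGA")

#' Declare a gene for the population simulator
#'
#' A gene is a named coding sequence with a purifying-constraint fraction:
#' `constrained_fraction` of its nucleotide sites are immutable (mutations
#' there are lethal and never observed), the rest evolve neutrally.
#'
#' @param name gene name.
#' @param cds_length_nt coding length in nucleotides, a multiple of 3.
#' @param constrained_fraction fraction f in \[0, 1\] of immutable sites.
#' @return an object of class `gene_model`.
#' @export
gene_model <- function(name, cds_length_nt, constrained_fraction) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  cds_length_nt <- as.integer(cds_length_nt)
  if (is.na(cds_length_nt) || cds_length_nt <= 0L || cds_length_nt %% 3L != 0L)
    stop("cds_length_nt for '", name, "' must be a positive multiple of 3")
  if (!is.numeric(constrained_fraction) || constrained_fraction < 0 ||
      constrained_fraction > 1)
    stop("constrained_fraction for '", name, "' must lie in [0, 1]")
  structure(list(name = name, cds_length_nt = cds_length_nt,
                 constrained_fraction = constrained_fraction),
            class = "gene_model")
}

#' Default gene roster for the simulator
#'
#' Eleven genes: the TDA biosynthesis cluster *tdaA*-*tdaF*, the two
#' roseobacticide-associated genes (sulfurase, glutathione S-transferase),
#' and the housekeeping baseline *gyrA*, *rpoB*, *recA*. Constrained
#' fractions are spread geometrically so that expected entropy scores of
#' adjacent genes differ about two-fold, which makes rank recovery
#' identifiable at desk scale; within the TDA cluster *tdaC* is the most
#' and *tdaB* the least constrained, and *recA* is fully constrained
#' (entropy exactly 0 regardless of log base). These fractions are
#' simulation truth parameters, not estimates for the real genes.
#'
#' @return a list of [gene_model()] objects.
#' @export
default_gene_models <- function() {
  spec <- list(
    c("tdaA", 1050, 0.62),
    c("tdaB",  444, 0.03),
    c("tdaC",  753, 0.79),
    c("tdaD",  243, 0.48),
    c("tdaE", 1146, 0.71),
    c("tdaF", 1170, 0.30),
    c("sulfurase", 1200, 0.965),
    c("gst",   660, 0.905),
    c("gyrA", 2640, 0.987),
    c("rpoB", 4140, 0.996),
    c("recA", 1041, 1.0)
  )
  lapply(spec, function(s) gene_model(s[1], as.integer(s[2]), as.numeric(s[3])))
}

#' Default seasonal schedule
#'
#' Two seasons per year: a summer/autumn peak and a winter trough, mirroring
#' the study cadence of twelve sampled years with population levels swinging
#' from a peak of 5.2 Log10 CFU per gram to below the 1 Log10 detection
#' limit.
#'
#' @param years number of simulated years.
#' @param peak_log10,trough_log10 Log10 CFU levels at seasonal extremes.
#' @return data.frame with columns `time_point`, `log10_cfu`, `season`.
#' @export
default_schedule <- function(years = 12, peak_log10 = 5.2, trough_log10 = 0) {
  yr <- seq_len(years) + 2008L
  data.frame(
    time_point = as.vector(rbind(paste0("sum", yr), paste0("win", yr))),
    log10_cfu = rep(c(peak_log10, trough_log10), years),
    season = rep(c("summer", "winter"), years),
    stringsAsFactors = FALSE
  )
}

#' Default per-event sample sizes
#'
#' Eleven sampling events with the per-event sequenced-isolate counts of the
#' study inventory (4 to 21 isolates per event), assigned to the first
#' eleven summer points of the schedule.
#'
#' @param schedule a schedule as returned by [default_schedule()].
#' @return named integer vector: time point -> isolates to draw.
#' @export
default_sample_sizes <- function(schedule = default_schedule()) {
  sizes <- c(6L, 7L, 4L, 11L, 4L, 14L, 9L, 19L, 8L, 21L, 11L)
  summers <- schedule$time_point[schedule$season == "summer"]
  if (length(summers) < length(sizes))
    sizes <- sizes[seq_along(summers)]
  stats::setNames(sizes, summers[seq_along(sizes)])
}

#' Configure a forward-time population simulation
#'
#' The simulated world is a single-species clonal population founded by
#' `n_clades` genotypes, each `founder_divergence_nt` substitutions away
#' from a common reference at unconstrained sites. The census follows the
#' seasonal Log10 schedule; genetically, drift acts on a scaled effective
#' population oscillating geometrically between `effective_size_cap` at
#' schedule peaks and `trough_effective_size` at troughs (hard-floored at
#' `n_clades`). By default every founder clade is guaranteed at least one
#' descendant each generation; `allow_extinction = TRUE` lifts that guard so
#' clade loss by drift can be studied.
#'
#' @param genes list of [gene_model()] objects (default [default_gene_models()]).
#' @param n_clades number of founder clades C.
#' @param founder_divergence_nt substitutions d separating each founder from
#'   the reference, placed at unconstrained sites.
#' @param mu per-site per-generation mutation probability at unconstrained
#'   sites.
#' @param generations_per_interval generations between consecutive schedule
#'   points.
#' @param schedule data.frame with `time_point` and `log10_cfu` columns.
#' @param effective_size_cap scaled census cap N_max used for drift.
#' @param trough_effective_size effective size at the schedule minimum
#'   (genetic layer only); set to `n_clades` for the harshest bottleneck.
#' @param sample_sizes named integer vector, time point -> isolates to draw.
#' @param lod limit of detection on the Log10 scale.
#' @param seawater_fraction probability a sampled isolate is labeled as
#'   seawater rather than bryozoan.
#' @param allow_extinction permit founder clades to be lost to drift.
#' @param seed integer RNG seed.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(genes = default_gene_models(),
                              n_clades = 8,
                              founder_divergence_nt = 106,
                              mu = 1e-4,
                              generations_per_interval = 8,
                              schedule = default_schedule(),
                              effective_size_cap = 2000,
                              trough_effective_size = 128,
                              sample_sizes = default_sample_sizes(schedule),
                              lod = 1.0,
                              seawater_fraction = 0.1,
                              allow_extinction = FALSE,
                              seed = 1) {
  if (inherits(genes, "gene_model")) genes <- list(genes)
  stopifnot(length(genes) >= 1L)
  genes <- lapply(genes, function(g) {
    if (!inherits(g, "gene_model")) do.call(gene_model, as.list(g)) else g
  })
  gene_names <- vapply(genes, `[[`, "", "name")
  if (anyDuplicated(gene_names)) stop("duplicate gene names in roster")
  n_clades <- as.integer(n_clades)
  stopifnot(n_clades >= 1L, mu >= 0, founder_divergence_nt >= 0,
            generations_per_interval >= 1L)
  if (effective_size_cap < n_clades)
    stop("effective_size_cap must be >= n_clades")
  if (trough_effective_size < 1)
    stop("trough_effective_size must be >= 1")
  stopifnot(is.data.frame(schedule),
            all(c("time_point", "log10_cfu") %in% names(schedule)),
            nrow(schedule) >= 1L)
  if (anyDuplicated(schedule$time_point))
    stop("schedule time points must be unique labels")
  if (length(sample_sizes)) {
    if (is.null(names(sample_sizes)) || any(!nzchar(names(sample_sizes))))
      stop("sample_sizes must be a named vector of time points")
    missing_tp <- setdiff(names(sample_sizes), schedule$time_point)
    if (length(missing_tp))
      stop("sampled time point(s) not in schedule: ",
           paste(missing_tp, collapse = ", "))
  }
  structure(list(
    genes = genes, n_clades = n_clades,
    founder_divergence_nt = as.integer(founder_divergence_nt),
    mu = mu, generations_per_interval = as.integer(generations_per_interval),
    schedule = schedule,
    effective_size_cap = as.integer(effective_size_cap),
    trough_effective_size = as.integer(trough_effective_size),
    sample_sizes = sample_sizes, lod = lod,
    seawater_fraction = seawater_fraction,
    allow_extinction = isTRUE(allow_extinction),
    seed = as.integer(seed)
  ), class = "simulation_config")
}

# genetic-layer census anchors: schedule Log10 levels mapped geometrically
# onto [trough_effective_size, effective_size_cap], floored at n_clades
# (or 1 when extinction is allowed)
census_anchors <- function(config) {
  lvl <- config$schedule$log10_cfu
  lo <- min(lvl); hi <- max(lvl)
  n_hi <- config$effective_size_cap
  n_lo <- min(config$trough_effective_size, n_hi)
  rel <- if (hi > lo) (lvl - lo) / (hi - lo) else rep(1, length(lvl))
  n <- round(exp(log(n_lo) + rel * (log(n_hi) - log(n_lo))))
  floor_n <- if (config$allow_extinction) 1L else config$n_clades
  pmin(n_hi, pmax(floor_n, as.integer(n)))
}

# per-generation census: geometric interpolation between anchors
census_trajectory <- function(config) {
  anchors <- census_anchors(config)
  gpi <- config$generations_per_interval
  n_pts <- length(anchors)
  gen_of_anchor <- (seq_len(n_pts) - 1L) * gpi + 1L
  total <- gen_of_anchor[n_pts]
  logn <- stats::approx(gen_of_anchor, log(anchors), xout = seq_len(total))$y
  floor_n <- if (config$allow_extinction) 1L else config$n_clades
  census <- pmin(config$effective_size_cap,
                 pmax(floor_n, as.integer(round(exp(logn)))))
  lvl <- stats::approx(gen_of_anchor, config$schedule$log10_cfu,
                       xout = seq_len(total))$y
  tp <- rep(NA_character_, total)
  tp[gen_of_anchor] <- config$schedule$time_point
  data.frame(generation = seq_len(total), census = census,
             log10_interp = lvl, time_point = tp, stringsAsFactors = FALSE)
}

# uniform draw among sense codons of the bacterial code (no internal stops
# in the reference; mutation can still create stops = pseudogenization)
random_reference <- function(total_nt) {
  codons <- apply(expand.grid(PP_BASES, PP_BASES, PP_BASES,
                              stringsAsFactors = FALSE)[, 3:1], 1L, paste,
                  collapse = "")
  sense <- setdiff(codons, PP_STOPS)
  drawn <- sample(sense, total_nt / 3L, replace = TRUE)
  match(unlist(strsplit(drawn, "", fixed = TRUE)), PP_BASES) - 1L
}

#' Simulate a seasonally bottlenecked clonal population
#'
#' Discrete generations of multinomial (Wright-Fisher) resampling with
#' Poisson mutation restricted to unconstrained sites; constrained sites
#' never mutate. Founders carry `founder_divergence_nt` substitutions each.
#' At every scheduled time point with a requested sample size, isolates are
#' drawn uniformly without replacement and labeled by founder ancestry.
#' Fully reproducible from `config$seed`.
#'
#' @param config a [simulation_config()].
#' @return list with elements `isolates` (list of isolate records, each with
#'   `isolate_id`, `time_point`, `source`, `clade` and named `sequences`)
#'   and `truth` (reference and founder sequences, constrained-site sets,
#'   census trajectory, per-anchor clade counts).
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, {
    genes <- config$genes
    gene_names <- vapply(genes, `[[`, "", "name")
    lens <- vapply(genes, `[[`, 0L, "cds_length_nt")
    offsets <- cumsum(c(0L, lens[-length(lens)]))
    total_nt <- sum(lens)
    C <- config$n_clades

    # fixed constrained-site sets, one draw per simulation
    constrained <- logical(total_nt)
    constrained_local <- vector("list", length(genes))
    names(constrained_local) <- gene_names
    for (i in seq_along(genes)) {
      n_con <- round(genes[[i]]$constrained_fraction * lens[i])
      site_order <- sample.int(lens[i])
      loc <- sort(site_order[seq_len(n_con)])
      constrained_local[[i]] <- loc
      constrained[offsets[i] + loc] <- TRUE
    }
    unconstrained_sites <- which(!constrained)
    n_unc <- length(unconstrained_sites)
    d <- config$founder_divergence_nt
    if (d > 0L && n_unc == 0L)
      stop("founder divergence requested but no unconstrained sites exist")
    if (d > n_unc)
      stop("founder_divergence_nt exceeds the number of unconstrained sites")

    reference <- random_reference(total_nt)
    # founder divergence is apportioned across genes proportionally to
    # unconstrained length (largest-remainder rounding), so per-gene
    # between-clade divergence density is representative of (1 - f_g);
    # placement within a gene is uniform over its unconstrained sites
    unc_by_gene <- lapply(seq_along(genes), function(i)
      setdiff(offsets[i] + seq_len(lens[i]), offsets[i] + constrained_local[[i]]))
    u_g <- lengths(unc_by_gene)
    alloc <- if (d > 0L && n_unc > 0L) {
      raw <- d * u_g / n_unc
      a <- floor(raw)
      rem <- d - sum(a)
      if (rem > 0L) {
        extra <- order(raw - a, decreasing = TRUE)[seq_len(rem)]
        a[extra] <- a[extra] + 1L
      }
      pmin(a, u_g)
    } else integer(length(genes))
    founders <- vector("list", C)
    for (k in seq_len(C)) {
      g <- reference
      for (i in seq_along(genes)) {
        if (alloc[i] == 0L) next
        sites <- unc_by_gene[[i]][sample.int(u_g[i], alloc[i])]
        g[sites] <- (g[sites] + sample.int(3L, alloc[i], replace = TRUE)) %% 4L
      }
      founders[[k]] <- g
    }

    traj <- census_trajectory(config)
    census <- traj$census
    anchor_gen <- which(!is.na(traj$time_point))
    names(anchor_gen) <- traj$time_point[anchor_gen]

    sizes <- config$sample_sizes
    for (tp in names(sizes)) {
      if (sizes[[tp]] > census[anchor_gen[[tp]]])
        stop("sample size ", sizes[[tp]], " exceeds census ",
             census[anchor_gen[[tp]]], " at time point '", tp, "'")
    }

    lambda <- config$mu * n_unc
    clade <- rep_len(seq_len(C), census[1L])
    diffs <- vector("list", census[1L])  # per-individual codes site*4 + base

    isolates <- list()
    clade_counts <- matrix(0L, nrow = length(anchor_gen), ncol = C,
                           dimnames = list(names(anchor_gen), NULL))

    materialize <- function(ix, tp) {
      n_iso <- length(ix)
      sources <- ifelse(stats::runif(n_iso) < config$seawater_fraction,
                        "seawater", "bryozoan")
      out <- vector("list", n_iso)
      for (j in seq_len(n_iso)) {
        i <- ix[j]
        g <- founders[[clade[i]]]
        v <- diffs[[i]]
        if (length(v)) g[v %/% 4L] <- v %% 4L
        full <- paste(PP_BASES[g + 1L], collapse = "")
        seqs <- stats::setNames(substring(full, offsets + 1L, offsets + lens),
                                gene_names)
        out[[j]] <- list(isolate_id = sprintf("%s_i%02d", tp, j),
                         time_point = tp, source = sources[j],
                         clade = clade[i], sequences = seqs)
      }
      out
    }

    total_gen <- length(census)
    for (t in seq_len(total_gen)) {
      if (t %in% anchor_gen) {
        tp <- names(anchor_gen)[match(t, anchor_gen)]
        clade_counts[tp, ] <- tabulate(clade, nbins = C)
        if (tp %in% names(sizes) && sizes[[tp]] > 0L) {
          ix <- sample.int(length(clade), sizes[[tp]])
          isolates <- c(isolates, materialize(ix, tp))
        }
      }
      if (t == total_gen) break
      n_child <- census[t + 1L]
      idx <- sample.int(length(clade), n_child, replace = TRUE)
      if (!config$allow_extinction) {
        # clade floor: each surviving parent clade keeps >= 1 descendant
        present <- unique(clade)
        missing <- setdiff(present, unique(clade[idx]))
        if (length(missing) && n_child >= length(present)) {
          slots <- sample.int(n_child, length(missing))
          for (m in seq_along(missing)) {
            cand <- which(clade == missing[m])
            idx[slots[m]] <- cand[sample.int(length(cand), 1L)]
          }
        }
      }
      clade <- clade[idx]
      diffs <- diffs[idx]
      if (lambda > 0) {
        nm <- stats::rpois(n_child, lambda)
        for (i in which(nm > 0L)) {
          v <- diffs[[i]]
          for (r in seq_len(nm[i])) {
            s <- unconstrained_sites[sample.int(n_unc, 1L)]
            cur <- founders[[clade[i]]][s]
            if (length(v)) {
              hit <- which(v %/% 4L == s)
              if (length(hit)) cur <- v[hit[length(hit)]] %% 4L
            }
            newb <- (cur + sample.int(3L, 1L)) %% 4L
            v <- c(v, s * 4L + newb)
          }
          diffs[[i]] <- v
        }
      }
    }

    as_strings <- function(g) {
      full <- paste(PP_BASES[g + 1L], collapse = "")
      stats::setNames(substring(full, offsets + 1L, offsets + lens), gene_names)
    }
    truth <- list(
      genes = data.frame(
        name = gene_names, cds_length_nt = lens,
        constrained_fraction = vapply(genes, `[[`, 0.0, "constrained_fraction"),
        n_unconstrained = lens - vapply(constrained_local, length, 0L),
        stringsAsFactors = FALSE),
      constrained_sites = constrained_local,
      reference = as_strings(reference),
      founders = lapply(founders, as_strings),
      census = traj,
      clade_counts = clade_counts,
      lod = config$lod,
      seed = config$seed
    )
    list(isolates = isolates, truth = truth)
  })
}

#' Isolate metadata table
#'
#' @param isolates isolate list from [simulate_population()].
#' @return data.frame with columns `isolate_id`, `time_point`, `source`,
#'   `clade`.
#' @export
isolate_metadata <- function(isolates) {
  data.frame(
    isolate_id = vapply(isolates, `[[`, "", "isolate_id"),
    time_point = vapply(isolates, `[[`, "", "time_point"),
    source = vapply(isolates, `[[`, "", "source"),
    clade = vapply(isolates, `[[`, 0L, "clade"),
    stringsAsFactors = FALSE
  )
}

#' Per-gene sequence sets from an isolate list
#'
#' @param isolates isolate list from [simulate_population()].
#' @return named list: gene -> named character vector (isolate id -> CDS).
#' @export
isolate_gene_sets <- function(isolates) {
  if (!length(isolates)) stop("empty isolate list")
  gene_names <- names(isolates[[1L]]$sequences)
  ids <- vapply(isolates, `[[`, "", "isolate_id")
  stats::setNames(lapply(gene_names, function(g) {
    stats::setNames(vapply(isolates, function(x) x$sequences[[g]], ""), ids)
  }), gene_names)
}

#' Generate a censored Log10 CFU abundance series
#'
#' Observation layer on top of the seasonal schedule: per time point,
#' `n_replicates` values are drawn Normal(scheduled level, `replicate_sd`);
#' values below the limit of detection are flagged censored and carry the
#' LOD as their numeric stand-in.
#'
#' @param config a [simulation_config()] providing schedule, LOD and seed.
#' @param replicate_sd replicate standard deviation (Log10 units), >= 0.
#' @param n_replicates replicates per time point, >= 1.
#' @param compartment label, e.g. "bryozoan" or "seawater".
#' @param schedule optional schedule override (data.frame like
#'   `config$schedule`).
#' @param seed RNG seed (defaults to `config$seed`; pass a different seed
#'   for a second compartment).
#' @return a [censored_series()].
#' @export
generate_abundance <- function(config, replicate_sd = 0.25, n_replicates = 3,
                               compartment = "bryozoan", schedule = NULL,
                               seed = config$seed) {
  stopifnot(inherits(config, "simulation_config"))
  if (replicate_sd < 0) stop("replicate_sd must be >= 0")
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  sched <- schedule %||% config$schedule
  with_seed(seed, {
    n_tp <- nrow(sched)
    vals <- stats::rnorm(n_tp * n_replicates,
                         mean = rep(sched$log10_cfu, each = n_replicates),
                         sd = replicate_sd)
    censored_series(
      time_point = rep(sched$time_point, each = n_replicates),
      log10_cfu = vals,
      replicate = rep(seq_len(n_replicates), n_tp),
      compartment = compartment,
      lod = config$lod
    )
  })
}

#' Write a simulated sample to disk
#'
#' One FASTA per gene (record ids are isolate ids), a metadata CSV, an
#' abundance CSV and, when truth is supplied, a truth JSON. The files
#' round-trip losslessly through the package readers.
#'
#' @param isolates isolate list from [simulate_population()].
#' @param abundance a [censored_series()] or list of them.
#' @param dir output directory (created if absent).
#' @param truth optional truth record from [simulate_population()].
#' @return invisibly, the paths written.
#' @export
write_sample <- function(isolates, abundance, dir, truth = NULL) {
  if (!length(isolates)) stop("empty isolate list")
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create output directory: ", dir)
  paths <- character(0)
  gene_sets <- isolate_gene_sets(isolates)
  for (g in names(gene_sets)) {
    p <- file.path(dir, paste0(g, ".fasta"))
    write_fasta(gene_sets[[g]], p)
    paths <- c(paths, p)
  }
  meta_path <- file.path(dir, "metadata.csv")
  utils::write.csv(isolate_metadata(isolates), meta_path, row.names = FALSE,
                   quote = FALSE)
  paths <- c(paths, meta_path)
  if (!is.null(abundance)) {
    series <- if (inherits(abundance, "censored_series")) list(abundance)
              else abundance
    ab_path <- file.path(dir, "abundance.csv")
    write_abundance_csv(series, ab_path)
    paths <- c(paths, ab_path)
  }
  if (!is.null(truth)) {
    truth_path <- file.path(dir, "truth.json")
    tr <- truth
    tr$census <- as.list(tr$census)
    tr$clade_counts <- unname(apply(truth$clade_counts, 1L, as.list))
    jsonlite::write_json(tr, truth_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    paths <- c(paths, truth_path)
  }
  pp_log("wrote ", length(paths), " files to ", dir)
  invisible(paths)
}
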