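#' Default pipeline configuration
#'
#' Every analysis tunable defaults to the study's printed value: 50 kb
#' compartment bins, 10 kb track/insulation bins, 1 Mb differential maps,
#' 50x50 saddle grid, 100 kb insulation window, ±20 kb border tolerance,
#' ±2.5 Mb domain flank, ±0.5 Mb site flank, 60-160 kb profile size window.
#' Simulation parameters default to the generator's calibration (alpha = 1,
#' kappa = 0.4) on a two-chromosome toy genome.
#'
#' @param seed Master seed; all stage seeds derive from it.
#' @return Nested configuration list (round-trips losslessly through YAML).
#' @export
default_config <- function(seed = 1) {
  list(
    seed = seed,
    genome = list(n_chrom = 2, chrom_length = 2.5e7),
    simulate = list(
      mean_block_len = 1e6, switch_fraction = 0.05, concordant = TRUE,
      decoy_fraction = 0, alpha = 1, kappa = 0.4, depth = 5e6, beta = 1,
      track_mean = 100, trans_fraction = 0.1,
      n_blurred = 120, n_buried = 60, site_size_range = c(4e4, 2.5e5)),
    resolutions = list(compartment = 5e4, track = 1e4, differential = 1e6),
    balance = list(mode = "tol", tol = 1e-4, n_iter = 1),
    saddle = list(n_quantiles = 50),
    insulation = list(window = 1e5, min_prominence = 0.2,
                      border_tolerance = 2e4, boundary_spacing = 5e5,
                      inside_boost = 3, depth = 8e6),
    stacks = list(domain_flank = 2.5e6, site_flank = 5e5,
                  size_window = c(6e4, 1.6e5)),
    sites = list(min_defined_frac = 0.5),
    stages = list(simulate = TRUE, hic = TRUE, compartments = TRUE,
                  insulation = TRUE, tracks = TRUE, sites = TRUE,
                  stats = TRUE))
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @return `read_config` returns the configuration list, with defaults
#'   filled in for omitted entries.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  merge_config(default_config(), user)
}

#' @rdname read_config
#' @param config Configuration list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    else base[[nm]] <- user[[nm]]
  }
  base
}

require_stage <- function(config, stage, needed_by) {
  check_that(isTRUE(config$stages[[stage]]),
             "stage '", needed_by, "' requires stage '", stage,
             "', which is disabled")
}

# mean track signal over each site's overlapping bins (any unit)
site_mean_signal <- function(track, sites) {
  hits <- GenomicRanges::findOverlaps(as_granges(sites),
                                      as_granges(track$bins))
  out <- stats::setNames(rep(NA_real_, nrow(sites)), sites$id)
  for (k in seq_len(nrow(sites))) {
    b <- S4Vectors::subjectHits(hits)[S4Vectors::queryHits(hits) == k]
    if (length(b)) out[k] <- mean(track$value[b], na.rm = TRUE)
  }
  out
}

balance_by_config <- function(map, cfg) {
  if (identical(cfg$balance$mode, "tol"))
    ice_normalize(map, tol = cfg$balance$tol)
  else
    ice_normalize(map, n_iter = cfg$balance$n_iter)
}

#' Run the full simulation-to-report analysis pipeline
#'
#' Simulates Hi-C maps for two conditions in two replicate cell lines from
#' one planted truth, then runs balancing, expected/O-E, EV1 compartment
#' calling, concordant switch classification, saddle and differential
#' saddle, TAD insulation and border overlap, IP/input track normalization,
#' site-level quadrant analysis with size-matched randomized controls, and
#' the Mann-Whitney/BH statistics, writing machine-readable artifacts and a
#' markdown report when `outdir` is given. Fully deterministic for a fixed
#' configuration seed.
#'
#' @param config Configuration list from [default_config()] /
#'   [read_config()], or a path to a YAML file.
#' @param outdir Optional output directory for TSV/BED/bedGraph artifacts
#'   and `report.md`.
#' @return List of results (`truth`, `ev1`, `switch`, `domains`, `saddles`,
#'   `insulation`, `tracks`, `sites`, `stats`), invisibly when `outdir` is
#'   given.
#' @export
run_pipeline <- function(config = default_config(), outdir = NULL) {
  if (is.character(config)) config <- read_config(config)
  config <- merge_config(default_config(), config)
  seed <- config$seed
  res <- list(config = config)

  check_that(isTRUE(config$stages$simulate),
             "file-based input is not configured; the pipeline requires ",
             "the simulate stage")
  gcfg <- config$genome
  genome <- genome_spec(stats::setNames(
    rep(gcfg$chrom_length, gcfg$n_chrom),
    paste0("chr", seq_len(gcfg$n_chrom))))
  scfg <- config$simulate
  params <- sim_params(alpha = scfg$alpha, kappa = scfg$kappa,
                       depth = scfg$depth, beta = scfg$beta,
                       track_mean = scfg$track_mean,
                       trans_fraction = scfg$trans_fraction)
  truth <- generate_compartment_profile(
    genome, bin_size = config$resolutions$compartment,
    mean_block_len = scfg$mean_block_len,
    switch_fraction = scfg$switch_fraction,
    concordant = scfg$concordant, decoy_fraction = scfg$decoy_fraction,
    seed = child_seed(seed, 1))
  gc <- simulate_gc(truth, seed = child_seed(seed, 2))
  res$truth <- truth
  res$genome <- genome

  blurred <- generate_sites(genome, scfg$n_blurred,
                            size_range = scfg$site_size_range,
                            seed = child_seed(seed, 30), class = "blurred")
  buried <- generate_sites(genome, scfg$n_buried,
                           size_range = scfg$site_size_range,
                           seed = child_seed(seed, 31), class = "buried")

  if (isTRUE(config$stages$hic)) {
    require_stage(config, "simulate", "hic")
    maps <- list()
    oes <- list()
    for (line in 1:2) for (cond in 1:2) {
      key <- paste0("line", line, "_cond", cond)
      m <- simulate_hic(truth, params,
                        seed = child_seed(seed, 10 + 2 * line + cond),
                        line = line, condition = cond)
      m <- balance_by_config(m, config)
      oes[[key]] <- observed_over_expected(m, expected_cis(m))
      maps[[key]] <- m
    }
    res$maps <- maps
    res$oe <- oes
    res$qc <- cis_trans_ratio(maps$line1_cond1)
    res$ps <- ps_curve(maps$line1_cond1)
    res$diffmap <- differential_map(maps$line1_cond1, maps$line1_cond2,
                                    config$resolutions$differential)
  }

  if (isTRUE(config$stages$compartments)) {
    require_stage(config, "hic", "compartments")
    ev <- lapply(res$oe, compute_ev1, gc = gc)
    res$ev1 <- ev
    res$switch <- classify_switch_bins(ev$line1_cond1, ev$line1_cond2,
                                       ev$line2_cond1, ev$line2_cond2)
    res$domains <- call_domains(ev$line1_cond1)
    nq <- config$saddle$n_quantiles
    res$saddles <- list(
      cond1 = saddle(res$oe$line1_cond1, ev$line1_cond1, nq),
      cond2 = saddle(res$oe$line1_cond2, ev$line1_cond2, nq))
    res$saddle_diff <- differential_saddle(res$saddles$cond1,
                                           res$saddles$cond2)
    res$saddle_corners <- lapply(res$saddles, saddle_corners)
  }

  if (isTRUE(config$stages$insulation)) {
    require_stage(config, "simulate", "insulation")
    icfg <- config$insulation
    tparams <- sim_params(alpha = scfg$alpha, kappa = 0,
                          depth = icfg$depth)
    tads <- lapply(1:2, function(cond) {
      sim <- simulate_tads(genome, bin_size = config$resolutions$track,
                           boundary_spacing = icfg$boundary_spacing,
                           inside_boost = icfg$inside_boost,
                           params = tparams,
                           seed = child_seed(seed, 20 + cond))
      m <- balance_by_config(sim$map, config)
      track <- insulation_score(m, window = icfg$window)
      list(truth = sim$boundaries, track = track,
           borders = call_borders(track, icfg$min_prominence))
    })
    res$insulation <- list(
      cond1 = tads[[1]], cond2 = tads[[2]],
      overlap = border_overlap(tads[[1]]$borders, tads[[2]]$borders,
                               icfg$border_tolerance))
  }

  if (isTRUE(config$stages$tracks)) {
    require_stage(config, "simulate", "tracks")
    tr <- lapply(1:2, function(cond) {
      raw <- simulate_track(truth, sites = blurred, params = params,
                            seed = child_seed(seed, 40 + cond),
                            bin_size = config$resolutions$track,
                            line = 1, condition = cond)
      lr <- log2_ip_over_input(cpm_normalize(raw$ip),
                               cpm_normalize(raw$input))
      z <- zscore_per_chromosome(lr)
      list(raw = raw, log_ratio = lr, zscore = z,
           smooth = smooth_nonzero(z, 3),
           rna = rna_log_cpm(raw$input))
    })
    names(tr) <- c("cond1", "cond2")
    res$tracks <- tr
  }

  if (isTRUE(config$stages$sites)) {
    require_stage(config, "compartments", "sites")
    require_stage(config, "tracks", "sites")
    mdf <- config$sites$min_defined_frac
    site_sets <- list(blurred = blurred, buried = buried,
                      random = randomize_sites(buried, genome,
                                               seed = child_seed(seed, 50)))
    quad <- lapply(site_sets, function(ss) {
      per_line <- lapply(1:2, function(line) {
        e1 <- site_mean_ev1(res$ev1[[paste0("line", line, "_cond1")]], ss,
                            min_defined_frac = mdf)
        e2 <- site_mean_ev1(res$ev1[[paste0("line", line, "_cond2")]], ss,
                            min_defined_frac = mdf)
        quadrant_classify(e1, e2)
      })
      list(per_line = per_line, summary = cross_line_quadrants(per_line))
    })
    res$sites <- list(sets = site_sets, quadrants = quad)
    # control comparison: site switching vs randomized control, line 1
    site_q <- quad$buried$per_line[[1]]
    rand_q <- quad$random$per_line[[1]]
    n_s <- site_q$n_informative
    n_r <- rand_q$n_informative
    k_s <- round(site_q$switch_proportion * n_s)
    k_r <- round(rand_q$switch_proportion * n_r)
    res$sites$control_test <- if (n_s > 0 && n_r > 0) {
      suppressWarnings(stats::prop.test(c(k_s, k_r), c(n_s, n_r)))$p.value
    } else NA_real_
    res$sites$expression <- site_expression(res$tracks$cond1$rna, buried)
  }

  if (isTRUE(config$stages$stats)) {
    require_stage(config, "sites", "stats")
    groups <- res$sites$quadrants$buried$per_line[[1]]$labels
    groups <- ifelse(groups %in% c("B-to-A", "B-stable"),
                     ifelse(groups == "B-stable", "B-to-B", groups),
                     NA_character_)
    vals <- lapply(res$tracks, function(t)
      site_mean_signal(t$zscore, res$sites$sets$buried))
    res$stats <- rescue_group_compare(vals, groups)
  }

  if (!is.null(outdir)) write_pipeline_outputs(res, outdir)
  if (is.null(outdir)) res else invisible(res)
}

write_pipeline_outputs <- function(res, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(outdir, ...)
  write_truth(res$truth, p("truth.tsv"))
  write_chrom_sizes(res$genome, p("genome.chrom.sizes"))
  if (!is.null(res$ev1)) {
    for (key in names(res$ev1)) {
      t <- res$ev1[[key]]
      write_bedgraph(binned_track(t$bins, t$ev1, t$resolution, "ev1"),
                     p(paste0("ev1_", key, ".bedGraph")))
    }
    dm <- res$domains
    write.table(data.frame(dm$chrom, dm$start, dm$end, dm$sign, dm$size),
                p("domains.bed"), sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    sw <- res$switch
    swdf <- cbind(res$truth$bins,
                  label = ifelse(is.na(sw$labels), "NA", sw$labels))
    write.table(swdf, p("switch_calls.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    for (cond in names(res$saddles))
      write.table(res$saddles[[cond]]$mean,
                  p(paste0("saddle_", cond, ".tsv")), sep = "\t",
                  quote = FALSE, row.names = FALSE, col.names = FALSE)
    write.table(res$saddle_diff, p("saddle_differential.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(res$insulation)) {
    it <- res$insulation$cond1$track
    write_bedgraph(binned_track(it$bins, it$score, it$resolution, "is"),
                   p("insulation_cond1.bedGraph"))
    b <- res$insulation$cond1$borders
    if (nrow(b))
      write.table(data.frame(b$chrom, b$start, b$start + it$resolution,
                             sprintf("border_%d", seq_len(nrow(b))),
                             b$prominence),
                  p("borders_cond1.bed"), sep = "\t", quote = FALSE,
                  row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(res$tracks))
    write_bedgraph(res$tracks$cond1$zscore, p("enrichment_z_cond1.bedGraph"))
  if (!is.null(res$sites)) {
    for (nm in names(res$sites$sets))
      write_sites(res$sites$sets[[nm]], p(paste0("sites_", nm, ".bed")))
    props <- do.call(rbind, lapply(names(res$sites$quadrants), function(nm) {
      s <- res$sites$quadrants[[nm]]$summary
      cbind(set = nm, s)
    }))
    write.table(props, p("site_quadrant_proportions.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  if (!is.null(res$stats))
    write.table(res$stats, p("group_tests.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  writeLines(render_report(res), p("report.md"))
  invisible(outdir)
}

render_report <- function(res) {
  lines <- c("# compartshift pipeline report", "",
             sprintf("Seed: %s", res$config$seed), "")
  if (!is.null(res$switch)) {
    lines <- c(lines, "## Compartment switching",
               sprintf("Genome proportion switching (concordant, both lines): %.3f%%",
                       100 * res$switch$proportion),
               sprintf("Counts: %s",
                       paste(names(res$switch$counts), res$switch$counts,
                             sep = "=", collapse = ", ")), "")
  }
  if (!is.null(res$saddle_corners)) {
    c1 <- res$saddle_corners$cond1
    lines <- c(lines, "## Saddle corners (cond1, 5x5 count-weighted)",
               sprintf("AA = %.3f, BB = %.3f, AB = %.3f", c1$AA, c1$BB,
                       c1$AB), "")
  }
  if (!is.null(res$insulation)) {
    lines <- c(lines, "## TAD borders",
               sprintf("Borders cond1: %d, cond2: %d, overlap fraction: %.3f",
                       nrow(res$insulation$cond1$borders),
                       nrow(res$insulation$cond2$borders),
                       res$insulation$overlap$fraction), "")
  }
  if (!is.null(res$sites)) {
    lines <- c(lines, "## Site quadrant proportions (mean ± SD across lines)")
    for (nm in names(res$sites$quadrants)) {
      s <- res$sites$quadrants[[nm]]$summary
      lines <- c(lines, sprintf("- %s: %s", nm,
                                paste(sprintf("%s %.1f%%±%.1f%%", s$label,
                                              100 * s$mean, 100 * s$sd),
                                      collapse = ", ")))
    }
    lines <- c(lines,
               sprintf("Buried vs random switching, two-proportion p = %.3g",
                       res$sites$control_test), "")
  }
  if (!is.null(res$stats)) {
    sig <- sum(!is.na(res$stats$q) & res$stats$q <= 0.05)
    lines <- c(lines, "## Group statistics",
               sprintf("%d of %d comparisons BH-significant at 5%%", sig,
                       nrow(res$stats)), "")
  }
  lines
}
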