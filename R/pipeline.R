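# Configuration-driven analysis pipeline: synthesize (or load) locus tables,
# run the statistical stages, and write TSV/JSON outputs with a manifest.

default_run_config <- function() {
  list(
    seed = 1L,
    out_dir = tempfile("micdiv_run_"),
    stages = c("simulate", "spectra", "allelestats", "sfs", "dnds",
               "linkage", "fn"),
    input = NULL,   # list(allele_fasta, counts_tsv, annotation, refs_fasta)
    sim = list(n_loci = 20, depth = 300, L = 400, theta = 0.02, rho = 0,
               kappa = 10, gc_bias = 1, coding_fraction = 0.75,
               target_dnds = 0.12),
    min_reads = 300, min_aa = 50, cloud_threshold = 0.10,
    rank_min_reads = 300,
    fn = list(p_S = 0.4, target_dnds = 0.15,
              planted = c(100, 30, 10), errors = c(600, 200, 50))
  )
}

validate_run_config <- function(config) {
  base <- default_run_config()
  for (nm in names(base)) if (is.null(config[[nm]])) config[[nm]] <- base[[nm]]
  for (nm in names(base$sim)) if (is.null(config$sim[[nm]]))
    config$sim[[nm]] <- base$sim[[nm]]
  for (nm in names(base$fn)) if (is.null(config$fn[[nm]]))
    config$fn[[nm]] <- base$fn[[nm]]
  required <- c("seed", "out_dir", "stages")
  for (nm in required) if (is.null(config[[nm]]))
    stop(sprintf("config field missing: %s", nm))
  unknown <- setdiff(config$stages, base$stages)
  if (length(unknown) > 0)
    stop("unknown stage(s): ", paste(unknown, collapse = ", "))
  if (!("simulate" %in% config$stages) && is.null(config$input))
    stop("config field missing: input (paths are required unless the ",
         "simulate stage is enabled)")
  # every stochastic stage gets an explicit derived seed
  config$stage_seeds <- stats::setNames(
    config$seed * 131L + seq_along(base$stages), base$stages)
  config
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the staged microdiversity analysis
#'
#' Chains synthesis (or loading) of per-locus allele tables with the
#' statistical stages; each stage writes TSV outputs under the configured
#' output directory, and a JSON manifest records the package version,
#' parameters, per-stage seeds, and outputs, sufficient to reproduce the
#' run bit for bit.
#'
#' @param config a named list (missing fields take defaults; see the
#'   vignette) or a path to a YAML/JSON file with the same structure
#' @return invisibly, a list with `tables`, per-stage `results`, and the
#'   manifest path
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) {
    config <- if (grepl("[.]json$", config))
      jsonlite::read_json(config, simplifyVector = TRUE) else
      yaml_load_file(config)
  }
  config <- validate_run_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  results <- list()

  tables <- NULL
  if ("simulate" %in% config$stages) {
    set.seed(config$stage_seeds[["simulate"]])
    sim <- config$sim
    tables <- list()
    for (i in seq_len(sim$n_loci)) {
      cfg <- sim_config(n = sim$depth, L = sim$L, theta = sim$theta,
                        rho = sim$rho, kappa = sim$kappa,
                        gc_bias = sim$gc_bias)
      gl <- generate_coding_locus(cfg, coding_fraction = sim$coding_fraction,
                                  target_dnds = sim$target_dnds,
                                  locus_id = sprintf("locus%03d", i))
      tables[[gl$table$locus_id]] <- gl$table
    }
    outputs <- c(outputs, write_locus_tables(
      tables, file.path(config$out_dir, "alleles.fasta"),
      file.path(config$out_dir, "counts.tsv"),
      file.path(config$out_dir, "annotation.tsv"),
      file.path(config$out_dir, "refs.fasta")))
  } else {
    tables <- read_locus_tables(config$input$allele_fasta,
                                config$input$counts_tsv,
                                config$input$annotation,
                                config$input$refs_fasta)
    tables <- filter_coding_loci(tables, config$min_aa)
  }
  deep <- filter_deep_loci(tables, config$min_reads)

  if ("spectra" %in% config$stages) {
    sp <- weighted_distance_spectrum(deep, "nucleotide", "all_pairs")
    null <- geometric_null(max(spectrum_mean(sp), 1e-6))
    results$spectra <- list(observed = sp, geometric = null)
    outputs <- c(outputs,
                 write_tsv(sp, file.path(config$out_dir, "distance_spectrum.tsv")),
                 write_tsv(null, file.path(config$out_dir, "geometric_null.tsv")))
  }
  if ("allelestats" %in% config$stages) {
    set.seed(config$stage_seeds[["allelestats"]])
    bands <- rank_frequency_bands(deep, min_reads = config$rank_min_reads)
    null <- null_rank_bands("asexual", theta = config$sim$theta,
                            L = config$sim$L,
                            depths = vapply(deep, `[[`, 0L, "depth"),
                            n_reps = 50, K = 2000)
    het <- vapply(deep, function(tb) heterozygosity(tb)$pi, 0)
    results$allelestats <- list(bands = bands, null = null, pi = het)
    outputs <- c(outputs, write_tsv(
      data.frame(rank = bands$ranks, t(bands$boundaries)),
      file.path(config$out_dir, "rank_frequency_bands.tsv")))
  }
  coding <- Filter(function(tb) !is.na(tb$designated_cds) &&
                     !is.null(tb$ref_b), deep)
  if ("sfs" %in% config$stages && length(coding) > 0) {
    dimorphs <- list(); depths_syn <- integer(0)
    for (tb in coding) {
      cl <- classify_sites(tb)
      dm <- extract_transition_dimorphs(cl, classes = c("syn_third",
                                                        "syn_first_LRS"))
      dimorphs[[tb$locus_id]] <- dm
      depths_syn <- c(depths_syn,
                      cl$R[cl$class %in% c("syn_third", "syn_first_LRS")])
    }
    all_dm <- do.call(rbind, dimorphs)
    sfs <- sfs_binned(all_dm, "ell_sfs", site_depths = depths_syn)
    results$sfs <- list(dimorphs = all_dm, sfs = sfs)
    outputs <- c(outputs, write_tsv(sfs, file.path(config$out_dir,
                                                   "synonymous_sfs.tsv")))
  }
  if ("dnds" %in% config$stages && length(coding) > 0) {
    per_locus <- lapply(coding, per_locus_weighted_dnds)
    pts <- data.frame(
      locus_id = names(per_locus),
      d_n = vapply(per_locus, `[[`, 0, "d_n"),
      d_s = vapply(per_locus, `[[`, 0, "d_s"))
    fit <- if (sum(!is.na(pts$d_s) & !is.na(pts$d_n)) >= 2)
      fit_dn_ds(pts, through_origin = TRUE) else NULL
    results$dnds <- list(per_locus = pts, fit = fit)
    outputs <- c(outputs, write_tsv(pts, file.path(config$out_dir,
                                                   "per_locus_dnds.tsv")))
  }
  if ("linkage" %in% config$stages) {
    set.seed(config$stage_seeds[["linkage"]])
    ens <- list()
    for (tb in deep) {
      ens <- c(ens, locus_pair_ensemble(tb, max_pairs = 200))
      if (length(ens) >= 2000) break
    }
    curves <- if (length(ens) > 0)
      linkage_curves(ens, bins = c(0, 25, 50, 100, 200, 400)) else NULL
    results$linkage <- list(n_pairs = length(ens), curves = curves)
    if (!is.null(curves))
      outputs <- c(outputs, write_tsv(curves, file.path(config$out_dir,
                                                        "linkage_curves.tsv")))
  }
  if ("fn" %in% config$stages) {
    fnc <- config$fn
    gen <- generate_error_class_table(fnc$planted, fn_dnds = fnc$target_dnds,
                                      p_S = fnc$p_S,
                                      n_errors_by_class = fnc$errors,
                                      seed = config$stage_seeds[["fn"]])
    sol <- solve_fn_mixture(gen$table, p_S = fnc$p_S,
                            target_dnds = fnc$target_dnds)
    results$fn <- list(table = gen$table, solution = sol)
    outputs <- c(outputs,
                 write_tsv(gen$table, file.path(config$out_dir,
                                                "error_class_table.tsv")),
                 write_tsv(sol$per_cell, file.path(config$out_dir,
                                                   "fn_solution.tsv")))
  }

  manifest <- list(
    package = "micdiv",
    version = as.character(utils::packageVersion("micdiv")),
    seed = config$seed,
    stage_seeds = as.list(config$stage_seeds),
    stages = config$stages,
    parameters = config[setdiff(names(config), c("stage_seeds", "stages"))],
    n_loci = length(tables), n_deep = length(deep),
    outputs = basename(outputs))
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, force = TRUE)
  invisible(list(tables = tables, results = results,
                 manifest = manifest_path))
}

# minimal YAML front end (flat/nested maps of scalars and lists), so run
# configurations can live in text files without extra dependencies
yaml_load_file <- function(path) {
  if (requireNamespace("yaml", quietly = TRUE))
    return(yaml::read_yaml(path))
  stop("reading YAML configs requires the yaml package; ",
       "pass a list or a JSON path instead")
}
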