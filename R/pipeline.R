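#' Run the full cohort characterization pipeline
#'
#' One reproducible run: generate a synthetic cohort (or accept a
#' pre-built one), annotate it, prioritize protein-truncating genes in
#' cases versus controls, titrate the causal-gene rank against control
#' count, compute discovery saturation curves, run the HWE/duplication
#' artifact analysis, and compute QC summaries. All stage outputs are
#' written as TSV/JSON under `out_dir`, together with a run manifest
#' (configuration snapshot, seeds, file digests, package version).
#' Re-running with the same configuration reproduces identical outputs.
#'
#' @param config a [generator_config()].
#' @param analysis an [analysis_config()].
#' @param out_dir output directory (created if needed).
#' @param cohort optional pre-built `synthetic_cohort` bundle (skips the
#'   generate stage's simulation but still writes its outputs).
#' @param saturation_perms permutations for the saturation curves
#'   (defaults to `analysis$saturation_permutations`).
#' @param quiet suppress per-stage progress messages.
#' @return Invisibly, a list with the main in-memory results
#'   (`rank_table`, `titration`, `saturation`, `hwe`, `qc`, `manifest`)
#'   and `out_dir`.
#' @export
run_pipeline <- function(config = generator_config(),
                         analysis = analysis_config(),
                         out_dir,
                         cohort = NULL,
                         saturation_perms = analysis$saturation_permutations,
                         quiet = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(stage, fmt, ...) {
    if (!quiet) {
      message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
    }
  }
  t_all <- proc.time()[["elapsed"]]
  run_stage <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
        call. = FALSE
      )
    })
    say(stage, "done in %.1fs", proc.time()[["elapsed"]] - t0)
    res
  }
  tsv <- function(x, name) {
    p <- file.path(out_dir, name)
    data.table::fwrite(x, p, sep = "\t")
    p
  }

  ## generate --------------------------------------------------------------
  sc <- run_stage("generate", {
    sc <- if (is.null(cohort)) generate_cohort(config) else cohort
    write_vcf(sc$cohort, file.path(out_dir, "cohort.vcf"))
    write_gene_models(sc$genes, file.path(out_dir, "genes.gff3"))
    write_chip_tsv(sc$chip, file.path(out_dir, "chip_genotypes.tsv"))
    write_window_depths(sc$windows, file.path(out_dir, "window_depths.tsv"))
    write_bed(sc$par, file.path(out_dir, "par.bed"))
    tsv(sc$cohort$samples, "samples.tsv")
    sc
  })
  x_chrom <- config$x_chrom

  ## annotate --------------------------------------------------------------
  ann <- run_stage("annotate", {
    a <- annotate_cohort(sc$cohort, sc$genes, sc$ref)
    tsv(a$ann, "annotation.tsv")
    tsv(a$gene_class, "gene_class.tsv")
    a
  })

  ## prioritize ------------------------------------------------------------
  rank_table <- run_stage("prioritize", {
    ev <- qualifying_variants(
      ann, case_ids(sc$cohort), control_ids(sc$cohort),
      config = analysis, x_chrom = x_chrom
    )
    tab <- rank_genes(ev)
    tsv(ev, "qualifying_events.tsv")
    tsv(tab, "gene_rank.tsv")
    tab
  })

  ## titrate ---------------------------------------------------------------
  titration <- run_stage("titrate", {
    n_ctrl <- length(control_ids(sc$cohort))
    rows <- lapply(seq_len(n_ctrl), function(nc) {
      tt <- control_titration(
        ann, sc$causal_gene, nc,
        n_permutations = analysis$titration_permutations,
        seed = (config$seed %||% 1L) + nc,
        config = analysis, x_chrom = x_chrom
      )
      data.table::data.table(
        n_controls = nc, mean_rank = tt$mean_rank, unranked = tt$unranked
      )
    })
    tt <- data.table::rbindlist(rows)
    tsv(tt, "titration.tsv")
    tt
  })

  ## saturate --------------------------------------------------------------
  saturation <- run_stage("saturate", {
    snv_curve <- novel_snv_curve(sc$cohort,
      n_perm = saturation_perms,
      seed = (config$seed %||% 1L) + 101L
    )
    ko_curve <- knockout_gene_curve(ann,
      n_perm = saturation_perms,
      seed = (config$seed %||% 1L) + 102L
    )
    tsv(snv_curve, "novel_snv_curve.tsv")
    tsv(ko_curve, "knockout_gene_curve.tsv")
    last <- nrow(ko_curve)
    jsonlite::write_json(
      list(
        last_step_mean_novel_snvs = snv_curve$mean_novel[last],
        last_step_mean_new_knockout_genes = ko_curve$mean_novel[last],
        extrapolation_20000_genes = extrapolate_cohort_size(
          20000, max(ko_curve$mean_novel[last], 1e-9)
        )
      ),
      file.path(out_dir, "saturation_summary.json"),
      auto_unbox = TRUE, digits = NA
    )
    list(snv = snv_curve, knockout = ko_curve)
  })

  ## hwe-dup ---------------------------------------------------------------
  hwe <- run_stage("hwe-dup", {
    autosomes <- setdiff(names(config$chrom_lengths), x_chrom)
    wd <- sc$windows
    cnv_sets <- lapply(sc$cohort$samples$sample_id, function(sm) {
      w <- wd[wd$sample_id == sm]
      segs <- list()
      wa <- w[w$chrom %in% autosomes]
      if (nrow(wa)) {
        segs$auto <- call_depth_cnv(wa, stats::median(wa$depth))
      }
      wx <- w[w$chrom == x_chrom]
      if (nrow(wx)) {
        segs$x <- call_depth_cnv(wx, stats::median(wx$depth))
      }
      res <- suppressWarnings(do.call(c, unname(segs)))
      sort(res)
    })
    names(cnv_sets) <- sc$cohort$samples$sample_id
    cnv_bed <- data.table::rbindlist(lapply(names(cnv_sets), function(sm) {
      g <- cnv_sets[[sm]]
      data.table::data.table(
        chrom = as.character(GenomicRanges::seqnames(g)),
        start = GenomicRanges::start(g) - 1L,
        end = GenomicRanges::end(g),
        state = g$state, sample_id = sm
      )
    }))
    data.table::fwrite(cnv_bed, file.path(out_dir, "cnv_segments.bed"),
      sep = "\t", col.names = FALSE
    )
    auto_rows <- sc$cohort$sites$chrom %in% autosomes
    auto_sites <- sc$cohort$sites[auto_rows]
    nn <- non_n_lengths(sc$ref)
    cats <- classify_site_categories(
      sites_granges(auto_sites), cnv_sets,
      genome_length = sum(nn[autosomes])
    )
    subset <- sc$cohort$samples$sample_id
    if ("ancestry" %in% names(sc$cohort$samples)) {
      main <- names(sort(table(sc$cohort$samples$ancestry), decreasing = TRUE))[1]
      subset <- sc$cohort$samples$sample_id[sc$cohort$samples$ancestry == main]
    }
    enr <- hwe_outlier_enrichment(
      sc$cohort, cats,
      site_ids = auto_sites$site_id,
      subset_samples = subset, config = analysis
    )
    tsv(enr$per_site, "hwe_per_site.tsv")
    mx <- male_x_het_summary(sc$cohort, sc$par, cnv_sets, x_chrom = x_chrom)
    tsv(mx, "male_x_het.tsv")
    jsonlite::write_json(
      list(
        outlier_rate = enr$outlier_rate,
        enrichment = enr$enrichment,
        hwe_subset = subset,
        male_x = mx
      ),
      file.path(out_dir, "hwe_enrichment.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows"
    )
    list(enrichment = enr, categories = cats, male_x = mx, cnv_sets = cnv_sets)
  })

  ## qc --------------------------------------------------------------------
  qc <- run_stage("qc", {
    autosomes <- setdiff(names(config$chrom_lengths), x_chrom)
    wd <- sc$windows[sc$windows$chrom %in% autosomes]
    cov <- wd[, .(mean_coverage = mean(depth)), by = sample_id]
    covv <- stats::setNames(cov$mean_coverage, cov$sample_id)
    conc <- concordance(sc$cohort, sc$chip, mean_coverage = covv)
    titv <- titv_ratio(sc$cohort$sites[kind == "SNV"])
    hh <- hom_het_ratio(sc$cohort)
    ko <- known_overlap(sc$cohort)
    tsv(conc, "concordance.tsv")
    tsv(hh$per_sample, "hom_het_ratio.tsv")
    tsv(ko$per_sample, "known_overlap.tsv")
    jsonlite::write_json(
      list(
        mean_concordance = attr(conc, "overall"),
        titv_ratio = titv,
        mean_hom_het_ratio = hh$mean,
        mean_known_fraction = ko$mean
      ),
      file.path(out_dir, "qc_summary.json"),
      auto_unbox = TRUE, digits = NA
    )
    list(concordance = conc, titv = titv, hom_het = hh, known = ko)
  })

  ## manifest --------------------------------------------------------------
  manifest <- run_stage("manifest", {
    files <- sort(setdiff(list.files(out_dir), "manifest.json"))
    digests <- tools::md5sum(file.path(out_dir, files))
    m <- list(
      tool = "lofcohort",
      version = as.character(utils::packageVersion("lofcohort")),
      seed = config$seed,
      generator_config = config_snapshot(config),
      analysis_config = unclass(analysis),
      files = stats::setNames(as.list(unname(digests)), files)
    )
    jsonlite::write_json(m, file.path(out_dir, "manifest.json"),
      auto_unbox = TRUE, digits = NA, null = "null"
    )
    m
  })
  say("run", "all stages complete in %.1fs", proc.time()[["elapsed"]] - t_all)

  invisible(list(
    out_dir = out_dir, cohort = sc, annotated = ann,
    rank_table = rank_table, titration = titration,
    saturation = saturation, hwe = hwe, qc = qc, manifest = manifest
  ))
}

# JSON-friendly snapshot of a generator config
config_snapshot <- function(config) {
  x <- unclass(config)
  x$chrom_lengths <- as.list(x$chrom_lengths)
  x
}
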