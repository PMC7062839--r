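#' Default analysis configuration
#'
#' Returns the full default configuration list that [run_pipeline()]
#' consumes; user configs (YAML or list) are merged over it.
#'
#' @return Nested named list.
#' @export
default_config <- function() {
  list(
    trait_a = list(path = NULL, schema = as.list(schema_beta_dialect()),
                   effect_scale = "beta", label = "A"),
    trait_b = list(path = NULL, schema = as.list(schema_or_dialect()),
                   effect_scale = "or", label = "B"),
    panel = list(path = NULL, format = "tsv"),
    genes = list(path = NULL, format = "bed"),
    filters = list(info = list(lo = 0.6, hi = 1.06), maf = 0.01),
    drop_ambiguous = TRUE,
    exclude_regions = list(),
    prune = list(r2 = 0.2, window_kb = 1000, enabled = TRUE),
    strata = c(1, 0.1, 0.01, 0.001),
    cfdr = list(min_count = 100),
    mr = list(enabled = FALSE, p_threshold = 1e-8, clump_r2 = 0.001,
              clump_kb = 10),
    thresholds = list(significant = 0.05, suggestive = 1e-5,
                      genome_wide = 5e-8),
    figures = TRUE,
    out_dir = NULL,
    seed = 1L
  )
}

merge_config <- function(base, user) {
  for (k in names(user)) {
    if (is.list(base[[k]]) && is.list(user[[k]]) && !is.null(names(user[[k]]))) {
      base[[k]] <- merge_config(base[[k]], user[[k]])
    } else {
      base[[k]] <- user[[k]]
    }
  }
  base
}

read_config <- function(cfg) {
  if (is.character(cfg) && length(cfg) == 1) cfg <- yaml::read_yaml(cfg)
  merge_config(default_config(), cfg)
}

#' Validate an analysis configuration
#'
#' Checks paths, schema completeness, filter and threshold sanity. Strata
#' given out of (descending) order are auto-sorted with a warning rather than
#' rejected.
#'
#' @param cfg Configuration list or path to a YAML file.
#' @return List with `config` (normalized), `issues` (tibble `field`,
#'   `message`) and `ok` (no errors found).
#' @export
validate_config <- function(cfg) {
  cfg <- read_config(cfg)
  issues <- list()
  bad <- function(field, msg) {
    issues[[length(issues) + 1L]] <<- tibble(field = field, message = msg)
  }
  for (tr in c("trait_a", "trait_b")) {
    p <- cfg[[tr]]$path
    if (is.null(p)) bad(paste0(tr, ".path"), "missing input path")
    else if (!file.exists(p)) bad(paste0(tr, ".path"), sprintf("file not found: %s", p))
    need <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
              "effect", "se", "p")
    miss <- setdiff(need, names(cfg[[tr]]$schema))
    if (length(miss)) bad(paste0(tr, ".schema"),
                          sprintf("schema lacks: %s", paste(miss, collapse = ", ")))
  }
  if ((isTRUE(cfg$prune$enabled) || isTRUE(cfg$mr$enabled))) {
    if (is.null(cfg$panel$path)) {
      bad("panel.path", "pruning/MR requires a reference panel path")
    } else if (!file.exists(cfg$panel$path)) {
      bad("panel.path", sprintf("file not found: %s", cfg$panel$path))
    }
  }
  if (!is.null(cfg$genes$path) && !file.exists(cfg$genes$path)) {
    bad("genes.path", sprintf("file not found: %s", cfg$genes$path))
  }
  if (is.null(cfg$out_dir)) bad("out_dir", "missing output directory")
  th <- cfg$thresholds
  if (!(th$genome_wide <= th$suggestive && th$suggestive <= th$significant)) {
    bad("thresholds", "thresholds must be monotone (genome_wide <= suggestive <= significant)")
  }
  if (is.unsorted(rev(cfg$strata))) {
    warn("Strata were not sorted descending; auto-sorting.")
  }
  cfg$strata <- sort(unique(cfg$strata), decreasing = TRUE)
  issues <- if (length(issues)) bind_rows(issues) else tibble(field = character(),
                                                              message = character())
  list(config = cfg, issues = issues, ok = nrow(issues) == 0)
}

#' Run the full pleiotropy analysis pipeline
#'
#' Executes read -> filter -> harmonize -> optional region exclusion ->
#' LD pruning -> fold-enrichment and conditional Q-Q curves (both
#' directions) -> conditional FDR in both directions -> conjunction ->
#' optional MR-Egger -> annotation and locus reports, writing result TSVs,
#' optional figures and a JSON manifest (input checksums, parameters, row
#' counts per stage, output files) under `out_dir`. Any stage error aborts
#' with the stage name after writing a partial manifest. Reruns with an
#' identical config and inputs produce byte-identical result tables.
#'
#' @param cfg Configuration list or YAML path; see [default_config()] and
#'   [validate_config()].
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(cfg) {
  v <- validate_config(cfg)
  if (!v$ok) {
    abort(paste0("Invalid configuration:\n",
                 paste(sprintf("- %s: %s", v$issues$field, v$issues$message),
                       collapse = "\n")))
  }
  cfg <- v$config
  dirs <- file.path(cfg$out_dir, c("tables", "curves", "figures"))
  for (d in dirs) dir.create(d, showWarnings = FALSE, recursive = TRUE)

  manifest <- list(parameters = cfg, stages = list(), outputs = character())
  inputs <- c(cfg$trait_a$path, cfg$trait_b$path, cfg$panel$path, cfg$genes$path)
  manifest$input_md5 <- as.list(tools::md5sum(unlist(inputs)))

  stage <- function(name, n_in, n_out) {
    manifest$stages[[length(manifest$stages) + 1L]] <<-
      list(stage = name, rows_in = n_in, rows_out = n_out,
           rows_dropped = n_in - n_out)
    inform(sprintf("[%s] %d -> %d rows", name, n_in, n_out))
  }
  fail <- function(name, e) {
    manifest$error <- list(stage = name, message = conditionMessage(e))
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, force = TRUE)
    abort(sprintf("Pipeline failed at stage '%s': %s", name,
                  conditionMessage(e)))
  }
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) fail(name, e))
  }

  a <- run_stage("read_a", {
    t <- read_sumstats(cfg$trait_a$path, unlist(cfg$trait_a$schema),
                       effect_scale = cfg$trait_a$effect_scale)
    stage("read_a", nrow(t) + attr(t, "n_rejected"), nrow(t)); t
  })
  b <- run_stage("read_b", {
    t <- read_sumstats(cfg$trait_b$path, unlist(cfg$trait_b$schema),
                       effect_scale = cfg$trait_b$effect_scale)
    stage("read_b", nrow(t) + attr(t, "n_rejected"), nrow(t)); t
  })
  ab <- run_stage("filter", {
    n0 <- nrow(a) + nrow(b)
    fi <- cfg$filters$info
    a2 <- filter_info(a, fi$lo, fi$hi)
    b2 <- filter_info(b, fi$lo, fi$hi)
    if (!is.null(cfg$filters$maf)) {
      a2 <- filter_maf(a2, cfg$filters$maf)
      b2 <- filter_maf(b2, cfg$filters$maf)
    }
    stage("filter", n0, nrow(a2) + nrow(b2)); list(a = a2, b = b2)
  })
  m <- run_stage("harmonize", {
    t <- harmonize(ab$a, ab$b, drop_ambiguous = cfg$drop_ambiguous)
    stage("harmonize", min(nrow(ab$a), nrow(ab$b)), nrow(t)); t
  })
  if (length(cfg$exclude_regions) > 0) {
    m <- run_stage("exclude_region", {
      n0 <- nrow(m)
      for (r in cfg$exclude_regions) {
        m <- exclude_region(m, genomic_region(r$chrom, r$start, r$end))
      }
      stage("exclude_region", n0, nrow(m)); m
    })
  }
  panel <- NULL
  if (!is.null(cfg$panel$path)) {
    panel <- run_stage("read_panel", {
      p <- if (identical(cfg$panel$format, "vcf")) read_panel_vcf(cfg$panel$path)
           else read_panel_tsv(cfg$panel$path)
      stage("read_panel", nrow(p$snps), nrow(p$snps)); p
    })
  }
  mp <- m
  if (isTRUE(cfg$prune$enabled)) {
    mp <- run_stage("prune", {
      t <- ld_prune(m, panel, r2_threshold = cfg$prune$r2,
                    window_kb = cfg$prune$window_kb)
      stage("prune", nrow(m), nrow(t)); t
    })
  }
  run_stage("curves", {
    n_curves <- 0L
    for (dir in c("A|B", "B|A")) {
      tag <- if (dir == "A|B") "a_given_b" else "b_given_a"
      fe <- fold_enrichment(mp, strata = cfg$strata, direction = dir)
      qq <- conditional_qq(mp, strata = cfg$strata, direction = dir)
      readr::write_tsv(as_tibble(fe),
                       file.path(cfg$out_dir, "curves",
                                 paste0("fold_enrichment_", tag, ".tsv")),
                       progress = FALSE)
      readr::write_tsv(as_tibble(qq),
                       file.path(cfg$out_dir, "curves",
                                 paste0("conditional_qq_", tag, ".tsv")),
                       progress = FALSE)
      if (isTRUE(cfg$figures)) {
        save_figure(autoplot(fe),
                    file.path(cfg$out_dir, "figures",
                              paste0("fold_enrichment_", tag, ".png")))
        save_figure(autoplot(qq),
                    file.path(cfg$out_dir, "figures",
                              paste0("conditional_qq_", tag, ".png")))
      }
      n_curves <- n_curves + nrow(fe) + nrow(qq)
    }
    stage("curves", nrow(mp), n_curves)
  })
  q_ab <- run_stage("cfdr_a_given_b", {
    r <- cfdr(m, direction = "A|B", min_count = cfg$cfdr$min_count)
    stage("cfdr_a_given_b", nrow(m), nrow(r$snps)); r
  })
  q_ba <- run_stage("cfdr_b_given_a", {
    r <- cfdr(m, direction = "B|A", min_count = cfg$cfdr$min_count)
    stage("cfdr_b_given_a", nrow(m), nrow(r$snps)); r
  })
  cc <- run_stage("conjunction", {
    t <- cfdr_conjunction(q_ab, q_ba)
    stage("conjunction", nrow(t), nrow(t)); t
  })
  mr_fit <- NULL
  if (isTRUE(cfg$mr$enabled)) {
    mr_fit <- run_stage("mr_egger", {
      exp_t <- ab$a |> dplyr::semi_join(m, by = "snp_id")
      out_t <- m |> select("snp_id", beta = "beta2", se = "se2", p = "p2")
      inst <- select_instruments(exp_t, out_t, panel,
                                 p_threshold = cfg$mr$p_threshold,
                                 clump_r2 = cfg$mr$clump_r2,
                                 clump_kb = cfg$mr$clump_kb)
      fit <- mr_egger(inst)
      stage("mr_egger", nrow(exp_t), fit$n_instruments); fit
    })
  }
  run_stage("report", {
    th <- cfg$thresholds
    per_snp <- call_significant(cc, th$significant, th$suggestive,
                                th$genome_wide, value = "q_ab") |>
      rename(tier_ab = "tier") |>
      arrange(.data$chrom, .data$pos, .data$snp_id)
    readr::write_tsv(per_snp, file.path(cfg$out_dir, "tables", "cfdr_per_snp.tsv"),
                     progress = FALSE)
    genes <- NULL
    if (!is.null(cfg$genes$path)) {
      genes <- read_gene_intervals(cfg$genes$path, format = cfg$genes$format)
      rep_ab <- build_locus_report(q_ab, m, genes, q_threshold = th$significant)
      readr::write_tsv(rep_ab,
                       file.path(cfg$out_dir, "tables", "loci_a_given_b.tsv"),
                       progress = FALSE)
      rep_ba <- build_locus_report(q_ba, m, genes, q_threshold = th$significant)
      readr::write_tsv(rep_ba,
                       file.path(cfg$out_dir, "tables", "loci_b_given_a.tsv"),
                       progress = FALSE)
    }
    if (!is.null(mr_fit)) {
      readr::write_tsv(dplyr::bind_cols(glance(mr_fit),
                                        mr_intercept_test(mr_fit)["verdict"]),
                       file.path(cfg$out_dir, "tables", "mr_egger.tsv"),
                       progress = FALSE)
    }
    if (isTRUE(cfg$figures)) {
      save_figure(plot_cfdr_manhattan(q_ab),
                  file.path(cfg$out_dir, "figures", "manhattan_a_given_b.png"))
      save_figure(plot_cfdr_manhattan(cc, value = "cc"),
                  file.path(cfg$out_dir, "figures", "manhattan_conjunction.png"))
    }
    stage("report", nrow(cc), nrow(cc))
  })

  manifest$outputs <- list.files(cfg$out_dir, recursive = TRUE)
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  invisible(manifest)
}

# figure writing must never sink a run: headless devices vary by platform
save_figure <- function(plot, path, width = 7, height = 4.5) {
  tryCatch({
    grDevices::png(path, width = width * 100, height = height * 100, res = 100)
    print(plot)
    grDevices::dev.off()
    invisible(path)
  }, error = function(e) {
    try(grDevices::dev.off(), silent = TRUE)
    warn(sprintf("Could not write figure %s: %s", path, conditionMessage(e)))
    invisible(NULL)
  })
}
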