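#' End-to-end pipeline orchestration
#'
#' `run_pipeline()` chains the stages with a single config: simulate
#' synthetic inputs, derive first exons, count, compute usage, compare
#' groups, and run the expression + enrichment side (size factors,
#' FPKM/TPM, expressed filter, DEG calls, set overlap, term enrichment).
#' Every run writes a log with parameters and the seed; outputs are plain
#' TSV/BED/GTF/SAM so each stage's output is a valid input to the next.
#'
#' @name pipeline_cli
NULL

#' Default pipeline configuration
#'
#' A nested list mirroring the YAML config file: simulation settings (see
#' [sim_config()]), alignment policy, and thresholds (expressed-filter
#' normalized count 3, fold-change 2, p 0.05, minimum term size 5).
#' Pipeline runs use a reduced read depth per sample (20,000 fragments) to
#' keep end-to-end runs light; the statistical stages are depth-agnostic.
#'
#' @return config list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    sim = list(reads_per_sample = 20000L, samples_per_group = 3L,
               strand = "+", paired = TRUE,
               mixtures = list(Min = c(0.3403, 0.1615, 0.4982),
                               DL = c(0.1869, 0.3111, 0.5020)),
               n_genes = 2000L, frac_de = 0.1, effect_log2fc = 2,
               nb_dispersion = 0.05),
    policy = list(min_overlap = 10L, min_mapq = 20L,
                  strandedness = "unstranded", count_unit = "read",
                  include_duplicates = TRUE),
    thresholds = list(expressed = 3, lfc = 1, p = 0.05, min_term_size = 5L),
    paths = list(annotation = NULL, alignments = NULL, sample_table = NULL,
                 count_matrix = NULL, gene_lengths = NULL,
                 annotation_map = NULL, gene_set = NULL, background = NULL)
  )
}

read_run_config <- function(config) {
  base <- default_config()
  if (is.null(config)) return(base)
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  merge_lists <- function(a, b) {
    for (nm in names(b)) {
      a[[nm]] <- if (is.list(a[[nm]]) && is.list(b[[nm]]))
        merge_lists(a[[nm]], b[[nm]]) else b[[nm]]
    }
    a
  }
  merge_lists(base, config)
}

cfg_to_sim_config <- function(cf) {
  s <- cf$sim
  mixtures <- lapply(s$mixtures, as.numeric)
  sim_config(strand = s$strand,
             mixtures = mixtures,
             reads_per_sample = as.integer(s$reads_per_sample),
             samples_per_group = as.integer(s$samples_per_group),
             paired = isTRUE(s$paired),
             seed = as.integer(cf$seed))
}

pipeline_log <- function(output_dir, msg) {
  path <- file.path(output_dir, "run.log")
  cat(msg, "\n", file = path, append = TRUE, sep = "")
  message(msg)
}

#' Run pipeline stages
#'
#' Subcommands: `simulate` (gene model GTF, per-sample SAMs, sample table,
#' count matrix, gene lengths, annotation map, truth tables), `first-exons`
#' (GTF -> BED of unique first-exon regions), `count` (alignments -> counts
#' TSV), `usage` (counts -> proportions TSV), `compare` (usage -> group
#' comparison TSV), `expression` (count matrix -> size factors, FPKM, TPM,
#' expressed gene list), `degs` (count matrix -> DEG table), `enrich` (DEG
#' set + annotation map -> enrichment TSV), and `all` (simulate then chain
#' everything).
#'
#' @param subcommand one of the stage names above.
#' @param config config list or YAML path; see [default_config()].  Paths
#'   in `config$paths` point at existing inputs for the non-simulating
#'   subcommands ('all' and 'simulate' generate them).
#' @param output_dir directory for artifacts (created if needed).
#' @param seed overrides `config$seed` when not NULL.
#' @return named list of written artifact paths, invisibly.
#' @export
run_pipeline <- function(subcommand = c("all", "simulate", "first-exons",
                                        "count", "usage", "compare",
                                        "expression", "degs", "enrich"),
                         config = NULL, output_dir = "promusage_out",
                         seed = NULL) {
  subcommand <- match.arg(subcommand)
  cf <- read_run_config(config)
  if (!is.null(seed)) cf$seed <- as.integer(seed)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  unlink(file.path(output_dir, "run.log"))
  pipeline_log(output_dir, sprintf("promusage %s | seed=%d | %s",
                                   subcommand, cf$seed,
                                   as.character(utils::packageVersion("promusage"))))
  artifacts <- list()

  do_simulate <- function() {
    scfg <- cfg_to_sim_config(cf)
    gtf <- file.path(output_dir, "gene_model.gtf")
    model <- simulate_gene_model(scfg, gtf_path = gtf)
    artifacts$gtf <<- gtf
    sample_rows <- list(); sams <- character(0)
    truth_rows <- list()
    for (g in names(scfg$mixtures)) {
      for (r in seq_len(scfg$samples_per_group)) {
        sid <- sprintf("%s_%d", g, r)
        sam <- file.path(output_dir, paste0(sid, ".sam"))
        sim <- simulate_alignments(model, scfg$mixtures[[g]],
                                   scfg$reads_per_sample, scfg,
                                   sample_id = sid, path = sam)
        sams[sid] <- sam
        sample_rows[[sid]] <- data.frame(sample_id = sid, group_id = g)
        truth_rows[[sid]] <- data.frame(
          sample_id = sid, promoter_id = names(sim$truth$read_share),
          expected_read_share = as.numeric(sim$truth$read_share),
          truth_count = as.integer(sim$truth$counts))
      }
    }
    st <- file.path(output_dir, "samples.tsv")
    utils::write.table(do.call(rbind, sample_rows), st, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    tt <- file.path(output_dir, "usage_truth.tsv")
    utils::write.table(do.call(rbind, truth_rows), tt, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    artifacts$sample_table <<- st; artifacts$alignments <<- sams
    artifacts$usage_truth <<- tt

    simc <- simulate_count_matrix(
      n_genes = as.integer(cf$sim$n_genes),
      frac_de = cf$sim$frac_de, effect_log2fc = cf$sim$effect_log2fc,
      nb_dispersion = cf$sim$nb_dispersion, seed = cf$seed)
    cm <- file.path(output_dir, "counts.tsv")
    write_matrix_tsv(simc$counts, cm)
    gl <- file.path(output_dir, "gene_lengths.tsv")
    utils::write.table(
      data.frame(gene_id = names(simc$lengths), length = simc$lengths),
      gl, sep = "\t", quote = FALSE, row.names = FALSE)
    dt <- file.path(output_dir, "deg_truth.tsv")
    utils::write.table(simc$truth, dt, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    sima <- simulate_annotation(rownames(simc$counts),
                                selected_pool = simc$truth$gene_id[simc$truth$is_de],
                                seed = cf$seed)
    am <- file.path(output_dir, "annotation_map.tsv")
    write_annotation_map(sima$annotation, am)
    bg <- file.path(output_dir, "background_genes.txt")
    writeLines(sima$annotation$background, bg)
    artifacts$count_matrix <<- cm; artifacts$gene_lengths <<- gl
    artifacts$deg_truth <<- dt; artifacts$annotation_map <<- am
    artifacts$background <<- bg
    pipeline_log(output_dir, sprintf(
      "simulate: %d samples x %d fragments; %d-gene count matrix",
      length(sams), scfg$reads_per_sample, nrow(simc$counts)))
    list(model = model, groups = simc$groups)
  }

  need <- function(path, what) {
    path <- unlist(path)
    if (is.null(path) || !all(file.exists(path)))
      stop("missing input for '", subcommand, "': ", what, " (",
           paste(unlist(path), collapse = ", "), ")", call. = FALSE)
    path
  }

  policy <- alignment_policy(
    min_overlap = cf$policy$min_overlap, min_mapq = cf$policy$min_mapq,
    strandedness = cf$policy$strandedness, count_unit = cf$policy$count_unit,
    include_duplicates = cf$policy$include_duplicates)

  result <- switch(
    subcommand,
    "simulate" = { do_simulate(); artifacts },
    "first-exons" = {
      gtf <- need(cf$paths$annotation, "annotation GTF")
      genes <- parse_gtf(gtf)
      bed <- file.path(output_dir, "first_exons.bed")
      fes <- derive_first_exons(genes[[1]])
      write_first_exons_bed(fes, bed)
      artifacts$first_exons_bed <- bed
      artifacts
    },
    "count" = , "usage" = , "compare" = {
      gtf <- need(cf$paths$annotation, "annotation GTF")
      st <- need(cf$paths$sample_table, "sample table TSV")
      sams <- need(cf$paths$alignments, "alignment files")
      genes <- parse_gtf(gtf)
      fes <- derive_first_exons(genes[[1]])
      groups <- read_sample_table(st)
      counts <- lapply(names(groups), function(sid) {
        count_first_exon_reads(sams[[sid]], fes, policy, sample_id = sid)
      })
      ct <- file.path(output_dir, "first_exon_counts.tsv")
      write_first_exon_counts(counts, ct)
      artifacts$counts <- ct
      if (subcommand != "count") {
        tab <- usage_proportions(counts, groups)
        ut <- file.path(output_dir, "usage.tsv")
        write_usage_tsv(tab, ut)
        artifacts$usage <- ut
        if (subcommand == "compare") {
          gids <- unique(unname(groups))
          cmp <- compare_usage_all(tab, gids[1], gids[2])
          cp <- file.path(output_dir, "usage_comparisons.tsv")
          write_usage_tsv(cmp, cp)
          artifacts$comparisons <- cp
        }
      }
      artifacts
    },
    "expression" = , "degs" = {
      cm <- need(cf$paths$count_matrix, "count matrix TSV")
      m <- read_count_matrix(cm)
      sf <- size_factors_median_of_ratios(m)
      utils::write.table(
        data.frame(sample_id = names(sf), size_factor = sf),
        file.path(output_dir, "size_factors.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
      artifacts$size_factors <- file.path(output_dir, "size_factors.tsv")
      if (subcommand == "expression") {
        gl <- need(cf$paths$gene_lengths, "gene length TSV")
        lens <- read_gene_lengths(gl)
        for (meth in c("FPKM", "TPM")) {
          p <- file.path(output_dir, paste0(tolower(meth), ".tsv"))
          write_matrix_tsv(normalize_expression(m, lens, meth), p)
          artifacts[[tolower(meth)]] <- p
        }
        expressed <- expressed_filter(m, sf, cf$thresholds$expressed)
        ep <- file.path(output_dir, "expressed_genes.txt")
        writeLines(expressed, ep)
        artifacts$expressed <- ep
      } else {
        st <- need(cf$paths$sample_table, "sample table TSV")
        groups <- read_sample_table(st)
        gids <- unique(unname(groups))
        degs <- call_degs(m, sf, names(groups)[groups == gids[1]],
                          names(groups)[groups == gids[2]],
                          lfc_threshold = cf$thresholds$lfc,
                          p_threshold = cf$thresholds$p)
        dp <- file.path(output_dir, "degs.tsv")
        write_usage_tsv(degs, dp)
        artifacts$degs <- dp
      }
      artifacts
    },
    "enrich" = {
      am <- need(cf$paths$annotation_map, "annotation map TSV")
      dg <- need(cf$paths$gene_set, "gene set file")
      ann <- read_annotation_map(am, cf$paths$background)
      gene_set <- scan(dg, what = character(), quiet = TRUE)
      res <- enrich(gene_set, ann, cf$thresholds$min_term_size)
      ep <- file.path(output_dir, "enrichment.tsv")
      write_usage_tsv(res, ep)
      artifacts$enrichment <- ep
      artifacts
    },
    "all" = {
      sim <- do_simulate()
      model <- sim$model
      fes <- derive_first_exons(model)
      bed <- file.path(output_dir, "first_exons.bed")
      write_first_exons_bed(fes, bed)
      artifacts$first_exons_bed <- bed
      groups <- read_sample_table(artifacts$sample_table)
      counts <- lapply(names(groups), function(sid) {
        count_first_exon_reads(artifacts$alignments[[sid]], fes, policy,
                               sample_id = sid)
      })
      ct <- file.path(output_dir, "first_exon_counts.tsv")
      write_first_exon_counts(counts, ct)
      artifacts$counts <- ct
      tab <- usage_proportions(counts, groups)
      ut <- file.path(output_dir, "usage.tsv")
      write_usage_tsv(tab, ut)
      artifacts$usage <- ut
      gids <- unique(unname(groups))
      cmp <- compare_usage_all(tab, gids[1], gids[2])
      cp <- file.path(output_dir, "usage_comparisons.tsv")
      write_usage_tsv(cmp, cp)
      artifacts$comparisons <- cp
      pipeline_log(output_dir, sprintf(
        "usage: %d promoters compared between %s and %s",
        nrow(cmp), gids[1], gids[2]))

      m <- read_count_matrix(artifacts$count_matrix)
      lens <- read_gene_lengths(artifacts$gene_lengths)
      sf <- size_factors_median_of_ratios(m)
      utils::write.table(
        data.frame(sample_id = names(sf), size_factor = sf),
        file.path(output_dir, "size_factors.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
      artifacts$size_factors <- file.path(output_dir, "size_factors.tsv")
      for (meth in c("FPKM", "TPM")) {
        p <- file.path(output_dir, paste0(tolower(meth), ".tsv"))
        write_matrix_tsv(normalize_expression(m, lens, meth), p)
        artifacts[[tolower(meth)]] <- p
      }
      expressed <- expressed_filter(m, sf, cf$thresholds$expressed)
      writeLines(expressed, file.path(output_dir, "expressed_genes.txt"))
      artifacts$expressed <- file.path(output_dir, "expressed_genes.txt")
      grp <- sim$groups
      g2 <- unique(unname(grp))
      degs <- call_degs(m, sf, names(grp)[grp == g2[1]],
                        names(grp)[grp == g2[2]],
                        lfc_threshold = cf$thresholds$lfc,
                        p_threshold = cf$thresholds$p)
      dp <- file.path(output_dir, "degs.tsv")
      write_usage_tsv(degs, dp)
      artifacts$degs <- dp
      ann <- read_annotation_map(artifacts$annotation_map, artifacts$background)
      called <- degs$gene_id[degs$is_deg]
      res <- enrich(called, ann, cf$thresholds$min_term_size)
      ep <- file.path(output_dir, "enrichment.tsv")
      write_usage_tsv(res, ep)
      artifacts$enrichment <- ep
      pipeline_log(output_dir, sprintf(
        "expression: %d expressed genes, %d DEGs, top term %s (q=%.3g)",
        length(expressed), length(called), res$term_id[1], res$q_value[1]))
      artifacts
    })
  pipeline_log(output_dir, "done")
  invisible(result)
}
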