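#' Pipeline configuration
#'
#' Builds a validated configuration for [pipeline_run_all()] from defaults
#' plus overrides. Unknown keys are rejected (a typo must never silently
#' fall back to a default). Defaults encode the package's reference
#' synthetic world: a 1 Mbp, 70% GC linear chromosome with 200 genes, half
#' of them carrying one planted motif instance (GGCCGG anchor 4 or GCCCG
#' anchor 4, fully methylated) in the -500/+100 upstream window, background
#' CG methylation at 0.1% of CG cytosines, and a directional 30x / 100 bp
#' bisulfite library at 0.995 conversion and 0.001 sequencing error.
#'
#' @param ... overrides of the defaults (see [pipeline_defaults()]).
#' @return a validated named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- pipeline_defaults()
  over <- list(...)
  if (length(over) == 1L && is.null(names(over)) && is.list(over[[1]]))
    over <- over[[1]]
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- modifyList(defaults, over)
  # motifs may arrive as list of motif_spec or as list(c(seq, anchor)) pairs
  cfg$motifs <- lapply(cfg$motifs, function(m) {
    if (inherits(m, "motif_spec")) m
    else if (is.list(m)) motif_spec(m$sequence %||% m[[1]],
                                    as.integer(m$anchor %||% m[[2]]),
                                    as.numeric(m$fraction %||% 1))
    else motif_spec(m[[1]], as.integer(m[[2]]))
  })
  assert_scalar_number(cfg$genome_length, "genome_length", lo = 1)
  assert_scalar_number(cfg$gc, "gc", lo = 0, hi = 1)
  assert_scalar_number(cfg$genes_with_motif_fraction,
                       "genes_with_motif_fraction", lo = 0, hi = 1)
  assert_scalar_number(cfg$conversion_rate, "conversion_rate", 0, 1)
  assert_scalar_number(cfg$error_rate, "error_rate", 0, 1)
  assert_scalar_number(cfg$epsilon, "epsilon", 1e-12, 1 - 1e-12)
  assert_scalar_number(cfg$alpha, "alpha", 0, 1)
  assert_scalar_number(cfg$window, "window", lo = 1)
  assert_scalar_number(cfg$up, "up", lo = 0)
  assert_scalar_number(cfg$down, "down", lo = 0)
  structure(cfg, class = c("pipeline_config", "list"))
}

#' @rdname pipeline_config
#' @export
pipeline_defaults <- function() {
  list(
    genome_length = 1e6, gc = 0.70, n_genes = 200L,
    gene_length = c(600L, 1800L), min_gap = 200L,
    motifs = default_motifs(), genes_with_motif_fraction = 0.5,
    background_rates = c(CG = 0.001, CHG = 0, CHH = 0),
    background_level = 1.0,
    coverage = 30, read_length = 100L,
    conversion_rate = 0.995, error_rate = 0.001,
    k = 16L, max_mismatch = NULL,
    epsilon = 0.005, alpha = 0.05, min_cov = 5L, min_level = 0.5,
    window = 250000L, up = 500L, down = 100L,
    k_values = c(5L, 6L), flank = 10L, min_support = 5L, motif_q_max = 0.05,
    seed = 1L
  )
}

#' Load a pipeline configuration from JSON
#' @param path JSON file with any subset of the configuration keys.
#' @return a `pipeline_config`.
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(raw$background_rates))
    raw$background_rates <- unlist(raw$background_rates)
  if (!is.null(raw$motifs) && is.data.frame(raw$motifs))
    raw$motifs <- lapply(seq_len(nrow(raw$motifs)), function(i)
      as.list(raw$motifs[i, ]))
  pipeline_config(raw)
}

#' Run the full synthetic-to-motifs pipeline
#'
#' Executes simulate -> map -> call -> landscape -> regions in order,
#' writing every artifact under `outdir` and returning (and writing) a
#' manifest with MD5 checksums plus a summary with context counts,
#' called-site totals, gene counts, the top motifs and — since the
#' simulator's truth is available — recovery metrics (per-site sensitivity
#' and precision; Jaccard of reported vs planted gene sets, both for the
#' any-site and for the motif-consensus gene table). A fixed config and seed
#' give identical manifests.
#'
#' The single `seed` expands deterministically into per-stage seeds
#' (`seed + 1` genome, `+2` annotation, `+3` methylome, `+4` reads) so each
#' stage is individually reproducible.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory (created if needed).
#' @param seed global seed; defaults to `config$seed`.
#' @param verbose log each stage to stderr.
#' @return invisibly, a list with the in-memory stage results
#'   (`genome`, `annotation`, `truth`, `reads`, `alignments`, `calls`,
#'   `profile`, `genes`, `genes_motif`, `motifs`, `summary`, `manifest`).
#' @export
pipeline_run_all <- function(config = pipeline_config(), outdir,
                             seed = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- as.integer(seed %||% config$seed)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(sprintf(...))
  pth <- function(f) file.path(outdir, f)

  say("[simulate] genome %g bp, GC %.2f", config$genome_length, config$gc)
  genome0 <- generate_genome(config$genome_length, config$gc, seed = seed + 1L)
  ann <- generate_annotation(genome0, config$n_genes, config$gene_length,
                             config$min_gap, seed = seed + 2L)
  pl <- plant_methylome(genome0, ann, motifs = config$motifs,
                        genes_with_motif_fraction =
                          config$genes_with_motif_fraction,
                        background_rates = config$background_rates,
                        background_level = config$background_level,
                        up = config$up, down = config$down, seed = seed + 3L)
  genome <- pl$genome
  reads <- simulate_reads(genome, pl$truth, coverage = config$coverage,
                          read_length = config$read_length,
                          conversion_rate = config$conversion_rate,
                          error_rate = config$error_rate, seed = seed + 4L)
  write_fasta(genome, pth("genome.fa"))
  write_gff3(ann, genome, pth("genes.gff3"))
  write_truth(pl$truth, pth("truth.tsv"))
  write_tsv(pl$planted, pth("planted_motifs.tsv"))
  write_fastq(reads, pth("reads.fastq"))
  write_read_origins(reads, pth("read_origins.tsv"))

  say("[map] %d reads, k = %d", nrow(reads), config$k)
  idx <- build_index(genome, k = config$k)
  aln <- map_reads(idx, reads, max_mismatch = config$max_mismatch)
  write_sam(aln, genome, pth("alignments.sam"))

  say("[call] epsilon %.4g, alpha %.3g", config$epsilon, config$alpha)
  counts <- pileup(aln, genome)
  calls <- call_methylation(counts, genome, epsilon = config$epsilon,
                            alpha = config$alpha, min_cov = config$min_cov,
                            min_level = config$min_level)
  write_cytosine_report(calls, pth("calls.tsv"))
  write_bedgraph(calls, pth("calls.bedGraph"))

  say("[landscape] window %g bp", config$window)
  prof <- window_profile(calls, genome_length(genome), config$window)
  write_tsv(as.data.frame(prof), pth("windows.tsv"))
  site_track(calls, bed_file = pth("sites.bed"))

  say("[regions] -%d/+%d around translation starts", config$up, config$down)
  regs <- upstream_regions(ann, up = config$up, down = config$down,
                           genome_length = genome_length(genome))
  write_tsv(regs, pth("upstream_regions.tsv"))
  genes <- genes_with_methylated_upstream(calls, regs)
  write_tsv(genes, pth("genes_methylated_upstream.tsv"))
  motifs <- anchored_motif_discovery(calls, genome,
                                     k_values = config$k_values,
                                     flank = config$flank,
                                     min_support = config$min_support,
                                     q_max = config$motif_q_max)
  write_tsv(motifs, pth("motifs.tsv"))
  genes_motif <- genes_with_methylated_upstream(calls, regs, motifs = motifs,
                                                genome = genome)
  write_tsv(genes_motif, pth("genes_motif_consensus.tsv"))

  summary <- pipeline_summary(calls, genes, genes_motif, motifs, pl, config)
  jsonlite::write_json(summary, pth("summary.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  files <- sort(setdiff(list.files(outdir), "manifest.json"))
  manifest <- list(
    config = config_for_json(config), seed = seed,
    files = data.frame(file = files,
                       md5 = unname(md5sum(file.path(outdir, files))),
                       stringsAsFactors = FALSE))
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  say("[done] %d artifacts in %s", length(files), outdir)

  invisible(list(genome = genome, annotation = ann, truth = pl$truth,
                 planted = pl$planted, reads = reads, alignments = aln,
                 calls = calls, profile = prof, genes = genes,
                 genes_motif = genes_motif, motifs = motifs,
                 summary = summary, manifest = manifest))
}

pipeline_summary <- function(calls, genes, genes_motif, motifs, pl, config) {
  called <- calls[calls$called, , drop = FALSE]
  ctx <- context_summary(calls)
  truth_key <- paste(pl$truth$pos0, pl$truth$strand)
  call_key <- paste(called$pos, called$strand)
  tp <- sum(call_key %in% truth_key)
  rec <- list(
    truth_sites = nrow(pl$truth),
    sensitivity = if (nrow(pl$truth)) tp / nrow(pl$truth) else NA,
    precision = if (nrow(called)) tp / nrow(called) else NA,
    jaccard_genes_any = jaccard(genes$gene_id, pl$planted$gene_id),
    jaccard_genes_motif = jaccard(genes_motif$gene_id, pl$planted$gene_id)
  )
  list(
    n_sites_called = nrow(called),
    context_counts = as.list(ctx),
    n_genes_methylated_upstream = nrow(genes),
    n_genes_motif_consensus = nrow(genes_motif),
    top_motifs = if (nrow(motifs)) head(motifs, 5) else list(),
    recovery = rec,
    params = config_for_json(config)
  )
}

jaccard <- function(a, b) {
  u <- union(a, b)
  if (!length(u)) return(NA_real_)
  length(intersect(a, b)) / length(u)
}

config_for_json <- function(config) {
  cfg <- unclass(config)
  cfg$motifs <- lapply(cfg$motifs, function(m)
    list(sequence = m$sequence, anchor = m$anchor, fraction = m$fraction))
  cfg$background_rates <- as.list(cfg$background_rates)
  cfg
}
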