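## End-to-end orchestration in simulation mode: simulate -> inject artifacts
## -> filter cascade -> spectrum/sharing -> region annotation -> clustering
## -> ancestral polarization -> CNV scan, with every intermediate written as
## a TSV under one run directory plus a manifest. Reruns with the same
## config + seed reproduce byte-identical outputs.

#' Run the full somatic-mutation tracing pipeline on simulated data
#'
#' @param config A [simulation_config()].
#' @param out_dir Output directory (created if needed).
#' @param filter A [filter_config()]; its replicate pairs are overridden by
#'   the simulation's pair.
#' @param cluster_threshold CEV threshold for cluster-number selection.
#' @param cnv_alpha,cnv_min_windows,cnv_log2_cut CNV segment calling
#'   parameters.
#' @param inject Logical: add labelled artifact sites before filtering.
#' @return Invisibly, a list with the major products (`sim`, `callset`,
#'   `report`, `spectrum`, `partition`, `selection`, `groups`, `ancestry`,
#'   `segments`, `manifest`).
#' @export
run_pipeline <- function(config = simulation_config(), out_dir,
                         filter = filter_config(),
                         cluster_threshold = 0.95,
                         cnv_alpha = 1e-3, cnv_min_windows = 3,
                         cnv_log2_cut = 0.5, inject = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)

  sim <- simulate_propagation(config)
  writeLines(truth_newick(sim$truth), p("truth_tree.nwk"))
  write_tsv(sim$truth$site_branch, p("truth_sites.tsv"))
  write_vcf(sim$table, p("true_variants.vcf"))

  table <- sim$table
  if (inject) {
    inj <- inject_artifacts(sim)
    table <- inj$table
    write_tsv(inj$sidecar, p("artifact_sidecar.tsv"))
  }
  write_vcf(table, p("variants.vcf"))

  filter$replicate_pairs <- sim$truth$replicate_pairs
  res <- run_cascade(table, filter)
  write_report(res$report, p("cascade_report.tsv"))
  write_report(res$callset, p("callset.tsv"))

  spec <- spectrum_summary(res$callset)
  write_report(spec, p("spectrum.tsv"))

  part <- partition_by_sharing(res$callset, sim$truth$replicate_map,
                               all_clones = sim$truth$clones)
  write_report(part, p("burden.tsv"))

  genes <- sim_gene_models(config$genome, seed = config$seed)
  region <- annotate_region(res$callset$sites, genes)
  write_tsv(data.frame(chrom = res$callset$sites$chrom,
                       pos = res$callset$sites$pos, region = region),
            p("regions.tsv"))

  mat <- build_matrix(part)
  sel <- select_cluster_number(mat, cluster_threshold)
  groups <- cluster_clones(mat, sel$k)
  write_report(groups, p("groups.tsv"))
  write_tsv(data.frame(component = seq_along(sel$cev), cev = sel$cev),
            p("cev_curve.tsv"))

  polar <- polarize_sites(res$callset, sim$panel)
  anc <- ancestor_counts(polar, part, groups)
  write_report(anc, p("ancestor_counts.tsv"))

  segments <- list()
  for (cl in names(sim$windows)) {
    seg <- call_segments(sim$windows[[cl]], alpha = cnv_alpha,
                         min_windows = cnv_min_windows,
                         log2_cut = cnv_log2_cut)
    if (nrow(seg)) seg$clone <- cl
    segments[[cl]] <- seg
  }
  segments <- if (length(segments)) do.call(rbind, segments) else
    data.frame()
  rownames(segments) <- NULL
  write_report(segments, p("cnv_segments.tsv"))

  manifest <- c(
    paste0("package: clonetrace ",
           as.character(utils::packageVersion("clonetrace"))),
    paste0("seed: ", config$seed),
    paste0("n_clones: ", config$n_clones),
    paste0("config_hash: ", config_hash(config)),
    paste0("final_somatic_sites: ", nrow(res$callset$sites)),
    paste0("groups: ", groups$k)
  )
  writeLines(manifest, p("MANIFEST"))

  invisible(list(sim = sim, callset = res$callset, report = res$report,
                 spectrum = spec, partition = part, selection = sel,
                 groups = groups, ancestry = anc, segments = segments,
                 manifest = manifest))
}

# order-stable hash of the configuration (digest-free: md5 of deparsed form)
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(config[order(names(config))]), tmp)
  unname(tools::md5sum(tmp))
}
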