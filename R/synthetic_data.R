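## Synthetic clonal-propagation datasets with recorded ground truth.
## A rooted propagation tree is drawn (founder branches from the root, then
## nested propagation within each founder lineage); somatic SNVs arise on
## branches under a Poisson model, so internal-branch mutations are shared by
## every descendant clone and terminal-branch mutations are unique to one
## clone — somatic mutations are treated as irreversible, so a mutated branch
## transmits its allele to all descendants. Genotypes are homozygous-alt on
## one haplotype chromosome, mirroring calls against a phased reference.

#' Simulation configuration
#'
#' Defaults mirror the study system this package models: 46 clones sampled
#' from one cultivar, eight founder lineages with group sizes
#' 19/7/4/2/3/1/1/9, one biological replicate pair (two sequencing runs of
#' one tree), mean sequencing depth 34x, a 10-line outgroup panel, and five
#' 10-25 kb deletions carried by four clones.
#'
#' @param n_clones Number of sampled clones.
#' @param founder_sizes Integer vector of leaves per founder lineage; must sum
#'   to `n_clones`.
#' @param topology `"bifurcating"`: nested random binary propagation within
#'   each founder lineage; `"star"`: every clone of a lineage descends
#'   directly from the founder node.
#' @param mu_internal,mu_terminal Poisson mean number of somatic SNVs per
#'   internal / terminal branch. The defaults put roughly nine unique
#'   mutations on record for every shared one, matching the strongly
#'   terminal-weighted sharing observed in clonal survey data.
#' @param class_weights Probabilities of the six strand-collapsed substitution
#'   classes (order of `SUBST_CLASSES`) used to draw ref/alt pairs; the
#'   default is the C:G>T:A-dominated spectrum typical of somatic SNVs.
#' @param genome A [genome_index()]; default [sim_genome()].
#' @param mean_depth Mean per-call read depth (Poisson), default 34.
#' @param depth_cap True-site depths are drawn from a Poisson truncated at
#'   this value (default 50) so that genuine somatic sites sit inside the
#'   cascade's accepted depth range; artifact sites violate it by
#'   construction.
#' @param read_length Read length in bp, used to convert depth to expected
#'   window read counts.
#' @param qual_shape,qual_scale Site quality for true sites is
#'   `80 + rgamma(shape, scale)`, keeping all true sites above the cascade's
#'   quality floor.
#' @param replicate Logical; simulate the first clone as two replicate
#'   samples (suffixes `_A`/`_B`).
#' @param n_outgroups Outgroup panel size (default 10).
#' @param artifacts Named integer vector of artifact site counts for
#'   [inject_artifacts()]: `multiallelic`, `het`, `replicate_discordant`,
#'   `high_depth`, `low_quality`.
#' @param genotype_error Per-call probability of replacing a true genotype
#'   code with `missing` (sequencing dropout); default 0.
#' @param cnv Data frame of planted deletions (`chrom`, `length`,
#'   `carrier_id`) where equal `carrier_id`s share one carrier clone, or
#'   `NULL` for none. Default: five deletions of 25/10/15/10/25 kb across
#'   four carriers.
#' @param window_size CNV scan window in bp (default 1000).
#' @param deletion_residual Fraction of the expected read count remaining
#'   inside a deleted interval (mis-mapped reads), default 0.01.
#' @param seed Integer seed; identical config + seed gives identical output.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(
    n_clones = 46,
    founder_sizes = c(19, 7, 4, 2, 3, 1, 1, 9),
    topology = c("bifurcating", "star"),
    mu_internal = 2,
    mu_terminal = 13.3,
    class_weights = c(0.417, 0.178, 0.175, 0.105, 0.075, 0.050),
    genome = sim_genome(),
    mean_depth = 34,
    depth_cap = 50,
    read_length = 150,
    qual_shape = 3,
    qual_scale = 20,
    replicate = TRUE,
    n_outgroups = 10,
    artifacts = c(multiallelic = 150, het = 150, replicate_discordant = 50,
                  high_depth = 50, low_quality = 50),
    genotype_error = 0,
    cnv = default_cnv_spec(),
    window_size = 1000,
    deletion_residual = 0.01,
    seed = 1) {
  topology <- match.arg(topology)
  if (sum(founder_sizes) != n_clones)
    stop("founder_sizes must sum to n_clones")
  if (any(founder_sizes < 1)) stop("founder_sizes must be >= 1")
  if (mu_internal < 0 || mu_terminal < 0 || genotype_error < 0 ||
      genotype_error > 1)
    stop("rates must be >= 0 and probabilities <= 1")
  if (length(class_weights) != 6 || any(class_weights < 0))
    stop("class_weights must be 6 non-negative values")
  structure(as.list(environment()), class = "simulation_config")
}

#' Default planted-deletion specification
#'
#' Five deletions (25, 10, 15, 10, 25 kb) on SPE2/SPE8/SPA2/SPE6/SPE2 across
#' four carrier clones, the first carrier holding two.
#' @return Data frame with `chrom`, `length`, `carrier_id`.
#' @export
default_cnv_spec <- function() {
  data.frame(
    chrom = c("SPE2", "SPE8", "SPA2", "SPE6", "SPE2"),
    length = c(25000, 10000, 15000, 10000, 25000),
    carrier_id = c(1L, 1L, 2L, 3L, 4L),
    stringsAsFactors = FALSE
  )
}

# truncated-Poisson sampler (values <= cap), inverse-CDF method
rpois_capped <- function(n, lambda, cap) {
  u <- stats::runif(n, 0, stats::ppois(cap, lambda))
  stats::qpois(u, lambda)
}

# build the propagation tree: edges (parent, child, terminal)
build_tree <- function(config) {
  leaves <- sprintf("C%02d", seq_len(config$n_clones))
  groups <- split(leaves, rep(seq_along(config$founder_sizes),
                              config$founder_sizes))
  edges <- list()
  node_i <- 0L
  add_edge <- function(parent, child, terminal)
    edges[[length(edges) + 1L]] <<- data.frame(
      parent = parent, child = child, terminal = terminal,
      stringsAsFactors = FALSE)
  grow <- function(parent, members) {
    if (length(members) == 1L) { add_edge(parent, members, TRUE); return() }
    if (config$topology == "star") {
      for (m in members) add_edge(parent, m, TRUE)
      return()
    }
    # random binary split into two non-empty parts
    k <- sample(seq_len(length(members) - 1L), 1L)
    left <- members[seq_len(k)]
    right <- members[-seq_len(k)]
    for (part in list(left, right)) {
      if (length(part) == 1L) add_edge(parent, part, TRUE)
      else {
        node_i <<- node_i + 1L
        nd <- paste0("N", node_i)
        add_edge(parent, nd, FALSE)
        grow(nd, part)
      }
    }
  }
  for (gi in seq_along(groups)) {
    members <- groups[[gi]]
    if (length(members) == 1L) {
      add_edge("root", members, TRUE)
    } else {
      f <- paste0("F", gi)
      add_edge("root", f, FALSE)
      grow(f, members)
    }
  }
  edges <- do.call(rbind, edges)
  edges$branch <- paste0(edges$parent, ">", edges$child)
  list(edges = edges, leaves = leaves,
       founder_of = stats::setNames(
         rep(seq_along(config$founder_sizes), config$founder_sizes), leaves))
}

# leaf -> vector of branch ids on its root path
leaf_paths <- function(edges, leaves) {
  parent_of <- stats::setNames(edges$parent, edges$child)
  branch_of <- stats::setNames(edges$branch, edges$child)
  lapply(stats::setNames(leaves, leaves), function(lf) {
    path <- character(0)
    node <- lf
    while (node != "root") {
      path <- c(branch_of[[node]], path)
      node <- parent_of[[node]]
    }
    path
  })
}

# descendant leaves of each branch
branch_leaf_sets <- function(paths) {
  out <- list()
  for (lf in names(paths))
    for (br in paths[[lf]]) out[[br]] <- c(out[[br]], lf)
  out
}

# draw (ref, alt) pairs according to strand-collapsed class weights
draw_substitutions <- function(n, class_weights) {
  reps <- list(
    `C:G>T:A` = rbind(c("C", "T"), c("G", "A")),
    `A:T>T:A` = rbind(c("A", "T"), c("T", "A")),
    `A:T>G:C` = rbind(c("A", "G"), c("T", "C")),
    `C:G>A:T` = rbind(c("C", "A"), c("G", "T")),
    `C:G>G:C` = rbind(c("C", "G"), c("G", "C")),
    `A:T>C:G` = rbind(c("A", "C"), c("T", "G"))
  )
  cls <- sample(SUBST_CLASSES, n, replace = TRUE, prob = class_weights)
  strand <- sample(1:2, n, replace = TRUE)
  ref <- character(n); alt <- character(n)
  for (i in seq_len(n)) {
    pair <- reps[[cls[i]]][strand[i], ]
    ref[i] <- pair[1]; alt[i] <- pair[2]
  }
  data.frame(ref = ref, alt = alt, stringsAsFactors = FALSE)
}

# global offsets 1..genome_size -> (chrom, pos)
offset_to_coord <- function(offset, genome) {
  cum <- cumsum(genome$length)
  idx <- findInterval(offset - 1, c(0, cum), rightmost.closed = FALSE)
  data.frame(chrom = genome$chrom[idx],
             pos = as.integer(offset - c(0, cum)[idx]),
             stringsAsFactors = FALSE)
}

#' Simulate a clonal propagation dataset
#'
#' Draws the propagation tree, assigns somatic SNVs to branches, builds the
#' multi-sample variant table (hom_alt at carried sites, hom_ref elsewhere),
#' the outgroup panel (carrying the ancestral = reference allele at every
#' somatic site), and per-window read-count tables reflecting the planted
#' deletions for each carrier clone.
#'
#' @param config A [simulation_config()].
#' @return A list of class `propagation_sim`:
#'   `truth` (`propagation_truth`: `edges`, `paths`, `branch_leaves`,
#'   `site_branch` data frame with per-site branch and carrier count,
#'   `cnvs`, `ancestor_alleles`, `replicate_map`, `clones`),
#'   `table` (a [variant_table()]), `panel` (an `outgroup_panel`),
#'   `windows` (named list of [window_count_table()]s, one per deletion
#'   carrier), and the `config`.
#' @export
simulate_propagation <- function(config = simulation_config()) {
  set.seed(config$seed)
  tree <- build_tree(config)
  edges <- tree$edges
  paths <- leaf_paths(edges, tree$leaves)
  bl_sets <- branch_leaf_sets(paths)

  # branch mutation counts
  mu <- ifelse(edges$terminal, config$mu_terminal, config$mu_internal)
  n_mut <- stats::rpois(nrow(edges), mu)
  total <- sum(n_mut)
  gsize <- genome_size(config$genome)
  if (total > gsize) stop("more mutations requested than genome positions")
  offsets <- sample.int(gsize, total)
  coords <- offset_to_coord(offsets, config$genome)
  subs <- draw_substitutions(total, config$class_weights)
  branch <- rep(edges$branch, n_mut)
  site_branch <- data.frame(
    chrom = coords$chrom, pos = coords$pos, ref = subs$ref, alt = subs$alt,
    branch = branch,
    terminal = rep(edges$terminal, n_mut),
    n_descendants = lengths(bl_sets)[branch],
    stringsAsFactors = FALSE
  )
  o <- order(site_branch$chrom, site_branch$pos)
  site_branch <- site_branch[o, , drop = FALSE]

  # sample roster: leaves, with the replicate clone expanded to two runs
  replicate_map <- NULL
  replicate_pairs <- list()
  samples <- tree$leaves
  if (config$replicate && config$n_clones >= 1) {
    rc <- tree$leaves[1]
    pair <- paste0(rc, c("_A", "_B"))
    samples <- c(pair, tree$leaves[-1])
    replicate_map <- stats::setNames(c(rc, rc), pair)
    replicate_pairs <- list(pair)
  }
  clone_of <- stats::setNames(
    ifelse(samples %in% names(replicate_map),
           replicate_map[samples], samples), samples)

  # genotypes: hom_alt where the sample's clone path carries the branch
  nsite <- nrow(site_branch)
  geno <- matrix("hom_ref", nsite, length(samples),
                 dimnames = list(NULL, samples))
  for (s in samples) {
    carried <- site_branch$branch %in% paths[[clone_of[[s]]]]
    geno[carried, s] <- "hom_alt"
  }
  if (config$genotype_error > 0) {
    drop <- matrix(stats::runif(length(geno)) < config$genotype_error,
                   nrow = nsite)
    geno[drop] <- "missing"
  }
  depth <- matrix(rpois_capped(nsite * length(samples), config$mean_depth,
                               config$depth_cap),
                  nsite, length(samples), dimnames = list(NULL, samples))
  qual <- 80 + stats::rgamma(nsite, shape = config$qual_shape,
                             scale = config$qual_scale)
  table <- variant_table(
    data.frame(chrom = site_branch$chrom, pos = site_branch$pos,
               ref = site_branch$ref, alt = site_branch$alt, qual = qual,
               stringsAsFactors = FALSE),
    geno, depth)

  # outgroup panel: ancestral allele is the reference base everywhere
  og_names <- sprintf("OG%02d", seq_len(config$n_outgroups))
  panel <- outgroup_panel(
    sites = site_branch[, c("chrom", "pos")],
    calls = matrix("ref", nsite, config$n_outgroups,
                   dimnames = list(NULL, og_names))
  )
  ancestor_alleles <- stats::setNames(
    rep("ref", nsite), site_key(site_branch$chrom, site_branch$pos))

  # planted deletions and window-count tables
  cnvs <- NULL
  windows <- list()
  if (!is.null(config$cnv) && nrow(config$cnv)) {
    spec <- config$cnv
    ids <- unique(spec$carrier_id)
    pool <- setdiff(tree$leaves, if (length(replicate_pairs)) tree$leaves[1])
    carriers <- sample(pool, length(ids))
    names(carriers) <- ids
    rows <- list()
    for (i in seq_len(nrow(spec))) {
      chrom <- spec$chrom[i]
      clen <- config$genome$length[config$genome$chrom == chrom]
      if (!length(clen)) stop("CNV chromosome not in genome: ", chrom)
      if (spec$length[i] >= clen) stop("deletion longer than chromosome")
      start <- sample.int(clen - spec$length[i], 1)
      rows[[i]] <- data.frame(
        clone = unname(carriers[as.character(spec$carrier_id[i])]),
        chrom = chrom, start = start, end = start + spec$length[i] - 1L,
        stringsAsFactors = FALSE)
    }
    cnvs <- do.call(rbind, rows)
    lambda <- config$mean_depth * config$window_size / config$read_length
    for (cl in unique(cnvs$clone)) {
      windows[[cl]] <- sim_window_counts(
        config$genome, config$window_size, lambda,
        deletions = cnvs[cnvs$clone == cl, , drop = FALSE],
        residual = config$deletion_residual)
    }
  }

  truth <- structure(list(
    edges = edges, paths = paths, branch_leaves = bl_sets,
    site_branch = site_branch, cnvs = cnvs,
    ancestor_alleles = ancestor_alleles,
    replicate_map = replicate_map, replicate_pairs = replicate_pairs,
    clones = tree$leaves, founder_of = tree$founder_of
  ), class = "propagation_truth")

  structure(list(truth = truth, table = table, panel = panel,
                 windows = windows, config = config),
            class = "propagation_sim")
}

#' Simulate a window-count table
#'
#' Tiles every chromosome with fixed windows and draws Poisson read counts
#' for a test and a reference sample; windows inside a planted deletion keep
#' only `residual` of the expected test count (scaled by overlap fraction for
#' partial windows).
#'
#' @param genome A [genome_index()].
#' @param window_size Window width in bp.
#' @param lambda Expected reads per full window.
#' @param deletions Optional data frame (`chrom`, `start`, `end`) of deleted
#'   intervals in the test sample.
#' @param residual Remaining fraction of coverage inside a deletion.
#' @return A [window_count_table()].
#' @export
sim_window_counts <- function(genome, window_size, lambda, deletions = NULL,
                              residual = 0.01) {
  rows <- list()
  for (i in seq_len(nrow(genome))) {
    starts <- seq(1L, genome$length[i], by = window_size)
    ends <- pmin(starts + window_size - 1L, genome$length[i])
    rows[[i]] <- data.frame(chrom = genome$chrom[i], start = starts,
                            end = ends, stringsAsFactors = FALSE)
  }
  w <- do.call(rbind, rows)
  frac_del <- numeric(nrow(w))
  if (!is.null(deletions) && nrow(deletions)) {
    for (j in seq_len(nrow(deletions))) {
      ov <- pmax(0, pmin(w$end, deletions$end[j]) -
                    pmax(w$start, deletions$start[j]) + 1)
      sel <- w$chrom == deletions$chrom[j]
      frac_del[sel] <- pmax(frac_del[sel], ov[sel] / (w$end - w$start + 1)[sel])
    }
  }
  mean_test <- lambda * ((1 - frac_del) + frac_del * residual)
  w$test <- stats::rpois(nrow(w), mean_test)
  w$ref <- stats::rpois(nrow(w), lambda)
  window_count_table(w, window_size)
}

#' Construct an outgroup panel
#'
#' @param sites Data frame with `chrom` and `pos`.
#' @param calls Character matrix (sites x panel lines) with values `"ref"`,
#'   `"alt"` or `NA` (missing).
#' @return An `outgroup_panel`.
#' @export
outgroup_panel <- function(sites, calls) {
  calls <- as.matrix(calls)
  if (nrow(calls) != nrow(sites)) stop("calls must have one row per site")
  bad <- setdiff(stats::na.omit(unique(as.vector(calls))), c("ref", "alt"))
  if (length(bad)) stop("panel calls must be 'ref', 'alt' or NA")
  structure(list(sites = as.data.frame(sites), calls = calls),
            class = "outgroup_panel")
}

#' Inject labelled artifact sites into a simulated variant table
#'
#' Appends one class of artifact site per cascade stage: multi-allelic
#' records, heterozygous-call sites (cross-haplotype mis-mapping),
#' replicate-discordant sites, collapsed-repeat sites with excessive depth,
#' and low-quality sites. True sites are left untouched; the returned sidecar
#' lists every artifact with its class.
#'
#' @param sim A `propagation_sim` from [simulate_propagation()].
#' @param counts Named integer vector of artifact counts (defaults to the
#'   config's `artifacts`).
#' @return A list: `table` (the augmented, position-sorted
#'   [variant_table()]), `sidecar` (data frame `chrom`, `pos`, `class`).
#' @export
inject_artifacts <- function(sim, counts = NULL) {
  config <- sim$config
  if (is.null(counts)) counts <- config$artifacts
  counts <- counts[counts > 0]
  table <- sim$table
  if (!length(counts))
    return(list(table = table,
                sidecar = data.frame(chrom = character(), pos = integer(),
                                     class = character())))
  set.seed(config$seed + 1L)
  if ("replicate_discordant" %in% names(counts) &&
      !length(sim$truth$replicate_pairs))
    stop("replicate_discordant artifacts need a configured replicate pair")
  samples <- table$samples
  nsamp <- length(samples)
  total <- sum(counts)
  used <- vt_site_keys(table)
  gsize <- genome_size(config$genome)
  coords <- NULL
  repeat {
    offs <- sample.int(gsize, total * 2)
    cand <- offset_to_coord(offs, config$genome)
    keep <- !(site_key(cand$chrom, cand$pos) %in% used) &
      !duplicated(site_key(cand$chrom, cand$pos))
    cand <- cand[keep, , drop = FALSE]
    if (nrow(cand) >= total) { coords <- cand[seq_len(total), ]; break }
  }
  bases <- c("A", "C", "G", "T")
  qual_true <- function(n) 80 + stats::rgamma(n, config$qual_shape,
                                              scale = config$qual_scale)
  depth_true <- function(n) rpois_capped(n, config$mean_depth, config$depth_cap)
  mk <- function(cls, n, i0) {
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      ref <- sample(bases, 1)
      alt <- sample(setdiff(bases, ref), if (cls == "multiallelic") 2 else 1)
      geno <- rep("hom_ref", nsamp); names(geno) <- samples
      depth <- depth_true(nsamp)
      qual <- qual_true(1)
      ncarry <- sample(1:3, 1)
      # never use the second replicate run as the sole carrier: its genotype
      # is overwritten below to keep non-discordant artifacts pair-consistent
      carry_pool <- if (length(sim$truth$replicate_pairs))
        setdiff(samples, sim$truth$replicate_pairs[[1]][2]) else samples
      carry <- sample(carry_pool, ncarry)
      geno[carry] <- "hom_alt"
      pair <- if (length(sim$truth$replicate_pairs))
        sim$truth$replicate_pairs[[1]] else NULL
      if (cls == "het") {
        pool <- setdiff(samples, c(carry, pair))
        geno[sample(pool, sample(1:3, 1))] <- "het"
      } else if (cls == "replicate_discordant") {
        geno[pair[1]] <- "hom_alt"
        geno[pair[2]] <- "hom_ref"
      }
      # keep non-discordant artifacts replicate-consistent so each class is
      # removed exactly by the stage it targets
      if (cls != "replicate_discordant" && !is.null(pair))
        geno[pair[2]] <- geno[pair[1]]
      if (cls == "high_depth") {
        idx <- which(geno == "hom_alt")
        depth[idx] <- config$depth_cap + 1L +
          stats::rpois(length(idx), 2 * config$depth_cap)
      } else if (cls == "low_quality") {
        qual <- stats::runif(1, 0, 79.9)
      }
      rows[[i]] <- list(
        site = data.frame(chrom = coords$chrom[i0 + i],
                          pos = coords$pos[i0 + i], ref = ref,
                          alt = paste(alt, collapse = ","), qual = qual,
                          stringsAsFactors = FALSE),
        geno = geno, depth = depth)
    }
    rows
  }
  all_rows <- list()
  sidecar <- list()
  i0 <- 0L
  for (cls in names(counts)) {
    n <- counts[[cls]]
    rws <- mk(cls, n, i0)
    all_rows <- c(all_rows, rws)
    sidecar[[cls]] <- data.frame(
      chrom = coords$chrom[i0 + seq_len(n)],
      pos = coords$pos[i0 + seq_len(n)],
      class = cls, stringsAsFactors = FALSE)
    i0 <- i0 + n
  }
  add_sites <- do.call(rbind, lapply(all_rows, `[[`, "site"))
  add_geno <- do.call(rbind, lapply(all_rows, `[[`, "geno"))
  add_depth <- do.call(rbind, lapply(all_rows, `[[`, "depth"))
  colnames(add_geno) <- samples
  colnames(add_depth) <- samples
  sites <- rbind(table$sites, add_sites)
  geno <- rbind(table$geno, add_geno)
  depth <- rbind(table$depth, add_depth)
  o <- order(sites$chrom, sites$pos)
  out <- variant_table(sites[o, ], geno[o, , drop = FALSE],
                       depth[o, , drop = FALSE])
  list(table = out, sidecar = do.call(rbind, sidecar))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Random non-overlapping gene intervals for a simulated genome
#'
#' Interval-only gene models (one exon spanning the gene, no CDS), sufficient
#' for gene-body vs intergenic annotation of simulated variants.
#'
#' @param genome A [genome_index()].
#' @param n_genes Number of genes to place.
#' @param gene_length Gene length in bp.
#' @param seed Integer seed.
#' @return A [gene_model_set()].
#' @export
sim_gene_models <- function(genome, n_genes = 300, gene_length = 3000,
                            seed = 1) {
  set.seed(seed)
  per_chrom <- table(sample(genome$chrom, n_genes, replace = TRUE,
                            prob = genome$length))
  rows <- list()
  gi <- 0L
  for (chrom in names(per_chrom)) {
    clen <- genome$length[genome$chrom == chrom]
    n <- per_chrom[[chrom]]
    slots <- floor(clen / (2 * gene_length))
    n <- min(n, slots)
    picks <- sort(sample.int(slots, n))
    for (p in picks) {
      gi <- gi + 1L
      start <- (p - 1L) * 2L * gene_length + 1L
      rows[[gi]] <- data.frame(
        gene_id = sprintf("G%04d", gi), chrom = chrom,
        strand = sample(c("+", "-"), 1),
        start = start, end = start + gene_length - 1L,
        stringsAsFactors = FALSE)
    }
  }
  genes <- do.call(rbind, rows)
  exons <- data.frame(gene_id = genes$gene_id, start = genes$start,
                      end = genes$end, stringsAsFactors = FALSE)
  gene_model_set(genes, exons,
                 data.frame(gene_id = character(), start = integer(),
                            end = integer(), phase = integer()))
}

#' Export the truth propagation tree as a newick string
#'
#' @param truth A `propagation_truth`.
#' @return Newick string (branch lengths = somatic mutation counts).
#' @export
truth_newick <- function(truth) {
  edges <- truth$edges
  mut_count <- table(truth$site_branch$branch)
  children_of <- split(edges$child, edges$parent)
  blen <- function(child) {
    br <- edges$branch[edges$child == child]
    n <- mut_count[br]
    if (is.na(n)) 0 else as.integer(n)
  }
  rec <- function(node) {
    kids <- children_of[[node]]
    if (is.null(kids)) return(node)
    inner <- paste(vapply(kids, function(k)
      paste0(rec(k), ":", blen(k)), character(1)), collapse = ",")
    paste0("(", inner, ")", if (node == "root") "" else node)
  }
  paste0(rec("root"), ";")
}
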