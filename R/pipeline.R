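# End-to-end orchestration: simulate or load inputs, reduce assays to
# rates, build and cluster the joint profile, rank candidates, optionally
# place transporters on the phylogeny, and emit a human-readable report
# plus a manifest sufficient to reproduce every output.

#' Configure a pipeline run
#'
#' For each data kind supply either a file path or let the simulator
#' preset provide it (the default). All seeds are derived from the single
#' `seed`, so a rerun with the same configuration is byte-identical.
#'
#' @param preset Simulator preset name (`"neurospora_like"`) or `NULL` when
#'   both `expr_file` and `assays_file` are given.
#' @param expr_file Optional expression-matrix TSV.
#' @param assays_file Optional long-format assay CSV.
#' @param alignment_file Optional aligned FASTA for the phylogeny stage.
#' @param clade_refs_file Optional two-column TSV (`name`, `clade`) of
#'   reference clade labels.
#' @param k Number of clusters for the dendrogram cut (default 5).
#' @param linkage Linkage for the joint clustering (default `"average"`).
#' @param bootstrap_reps Bootstrap replicates for the tree stage (default
#'   100; used only when an alignment is supplied).
#' @param noise_cv Simulator noise CV (preset runs only).
#' @param decoupled Simulate the expression-decoupled scenario (preset
#'   runs only).
#' @param r_threshold Decoupling-suspect threshold for the report.
#' @param seed Master seed.
#' @return A `run_config` list.
#' @export
pipeline_config <- function(preset = "neurospora_like", expr_file = NULL,
                            assays_file = NULL, alignment_file = NULL,
                            clade_refs_file = NULL, k = 5,
                            linkage = "average", bootstrap_reps = 100,
                            noise_cv = 0.1, decoupled = FALSE,
                            r_threshold = 0.5, seed = 1) {
  have_files <- !is.null(expr_file) && !is.null(assays_file)
  if (is.null(preset) && !have_files)
    stop("supply a preset or both expr_file and assays_file")
  if (!is.null(preset) && have_files)
    stop("supply either a preset or input files, not both")
  structure(list(preset = preset, expr_file = expr_file,
                 assays_file = assays_file, alignment_file = alignment_file,
                 clade_refs_file = clade_refs_file, k = k, linkage = linkage,
                 bootstrap_reps = bootstrap_reps, noise_cv = noise_cv,
                 decoupled = decoupled, r_threshold = r_threshold,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full expression-uptake correlation pipeline
#'
#' Stages: obtain expression + assays (simulate or read), reduce assays to
#' the uptake-rate matrix, fuse and cluster the joint profile, rank
#' candidates per sugar, optionally build the bootstrap NJ tree and assign
#' clades, then write the report bundle under `outdir`: `expression.tsv`,
#' `assays.csv`, `uptake_matrix.tsv` (+ flags JSON), `joint_matrix.tsv`
#' (dendrogram leaf order, heatmap-ready), `dendrogram.nwk`,
#' `clusters.tsv`, `rankings.tsv`, `report.md`, `manifest.json`, and when
#' an alignment is supplied `tree.nwk` + `clades.tsv`. A stage failure
#' aborts with the stage name.
#'
#' @param cfg A `run_config` from [pipeline_config()].
#' @param outdir Output directory (created if needed).
#' @return List with the in-memory results (`uptake`, `joint`, `dendrogram`,
#'   `clusters`, `rankings`, `clades`, `report`, `manifest`), invisibly.
#' @export
run_pipeline <- function(cfg, outdir) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  truth <- NULL
  if (!is.null(cfg$preset)) {
    truth <- stage("simulate", {
      if (cfg$preset != "neurospora_like")
        stop("unknown preset '", cfg$preset, "'")
      simulate_transportome(preset_neurospora_like(
        noise_cv = cfg$noise_cv, decoupled = cfg$decoupled, seed = cfg$seed))
    })
    expr <- truth$expression
    # cell-level observation noise already sits in uptake_observed; the
    # assays carry those observed rates so the matrix reduction sees it
    assays <- stage("simulate", {
      obs <- truth$uptake_observed
      tmp <- truth; tmp$uptake_true <- obs
      simulate_uptake_assays(tmp, c0_uM = max(1000, 20 * max(obs)),
                             noise_cv = 0, seed = cfg$seed + 1L)
    })
  } else {
    expr <- stage("read_expression", {
      if (!file.exists(cfg$expr_file))
        stop("expression file not found: ", cfg$expr_file)
      read_expression_tsv(cfg$expr_file)
    })
    assays <- stage("read_assays", {
      if (!file.exists(cfg$assays_file))
        stop("assay file not found: ", cfg$assays_file)
      read_assays_csv(cfg$assays_file)
    })
  }
  um <- stage("rates", build_uptake_matrix(assays))
  jp <- stage("joint_profile", build_joint_profile(um, expr))
  dmat <- stage("distance", correlation_distance_matrix(jp))
  dend <- stage("cluster", average_linkage_cluster(dmat, linkage = cfg$linkage))
  clusters <- stage("cut", cut_clusters(dend, k = cfg$k))
  rankings <- stage("rank", rank_candidates(jp, dend, k = cfg$k))
  clades <- NULL
  tree <- NULL
  if (!is.null(cfg$alignment_file)) {
    tree <- stage("tree", {
      aln <- read_fasta_alignment(cfg$alignment_file)
      bootstrap_support(aln, n_reps = cfg$bootstrap_reps,
                        seed = cfg$seed + 2L)
    })
    if (!is.null(cfg$clade_refs_file)) {
      clades <- stage("clades", {
        refs <- utils::read.delim(cfg$clade_refs_file,
                                  stringsAsFactors = FALSE)
        assign_clades(tree, stats::setNames(refs[[2L]], refs[[1L]]))
      })
    }
  }
  uptake_means <- rowMeans(um$rates, na.rm = TRUE)
  report <- make_report(rankings, clades = clades, clusters = clusters,
                        uptake_means = uptake_means,
                        r_threshold = cfg$r_threshold)
  manifest <- list(
    package_version = as.character(utils::packageVersion("transportome")),
    seed = cfg$seed,
    config = unclass(cfg)[!vapply(unclass(cfg), is.null, TRUE)])

  # --- write bundle ---
  write_expression_tsv(expr, file.path(outdir, "expression.tsv"))
  write_assays_csv(assays, file.path(outdir, "assays.csv"))
  write_uptake_tsv(um, file.path(outdir, "uptake_matrix.tsv"))
  ord <- dend$labels[dend$order]
  write_expression_tsv(jp$values[ord, , drop = FALSE],
                       file.path(outdir, "joint_matrix.tsv"))
  ape::write.tree(ape::as.phylo(dend), file.path(outdir, "dendrogram.nwk"))
  utils::write.table(
    data.frame(label = names(clusters), cluster = clusters,
               role = jp$roles[match(names(clusters), rownames(jp$values))]),
    file.path(outdir, "clusters.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  rank_df <- do.call(rbind, lapply(names(rankings), function(s)
    cbind(sugar = s, rankings[[s]])))
  utils::write.table(rank_df, file.path(outdir, "rankings.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(report$markdown, file.path(outdir, "report.md"))
  if (!is.null(tree)) write_newick(tree, file.path(outdir, "tree.nwk"))
  if (!is.null(clades))
    utils::write.table(data.frame(name = names(clades), clade = clades),
                       file.path(outdir, "clades.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(truth = truth, uptake = um, joint = jp, dendrogram = dend,
                 clusters = clusters, rankings = rankings, tree = tree,
                 clades = clades, report = report, manifest = manifest))
}

#' Candidate report: top hits per sugar with flags
#'
#' Summarizes, per sugar, the top-`top_n` candidate genes with their
#' Pearson r, cluster co-membership, and (when available) phylogenetic
#' clade. Flags constant-expression genes, and raises a decoupling-suspect
#' flag for any sugar with nonzero uptake whose best gene correlation stays
#' below `r_threshold` — the signature of a transporter regulated post-
#' transcriptionally rather than at the expression level.
#'
#' @param rankings Output of [rank_candidates()].
#' @param clades Optional named vector gene -> clade (`"unplaced"` passes
#'   through verbatim).
#' @param clusters Optional named cluster ids from [cut_clusters()].
#' @param uptake_means Optional named mean uptake per sugar (used for the
#'   decoupling flag; sugars with zero mean uptake are never suspects).
#' @param r_threshold Decoupling-suspect threshold on max r (default 0.5).
#' @param top_n Candidates listed per sugar (default 5).
#' @return List with `markdown` (character vector of lines), `table`
#'   (long data frame), `decoupling_suspects` (character vector).
#' @export
make_report <- function(rankings, clades = NULL, clusters = NULL,
                        uptake_means = NULL, r_threshold = 0.5, top_n = 5) {
  lines <- c("# Transporter candidate report", "")
  suspects <- character(0)
  tabs <- list()
  if (length(rankings) == 0L)
    lines <- c(lines, "_No sugars ranked (empty input)._")
  for (s in names(rankings)) {
    rk <- rankings[[s]]
    lines <- c(lines, paste0("## ", s), "")
    if (nrow(rk) == 0L) {
      lines <- c(lines, "_No candidate genes._", "")
      next
    }
    max_r <- suppressWarnings(max(rk$r, na.rm = TRUE))
    nonzero <- is.null(uptake_means) || isTRUE(uptake_means[[s]] > 0)
    if (nonzero && (!is.finite(max_r) || max_r < r_threshold)) {
      suspects <- c(suspects, s)
      lines <- c(lines, paste0(
        "**Decoupling suspect:** measurable uptake but no gene with r >= ",
        format(r_threshold),
        " - consider post-transcriptional regulation."), "")
    }
    top <- utils::head(rk, top_n)
    top$clade <- if (is.null(clades)) NA_character_ else
      ifelse(top$gene %in% names(clades), clades[top$gene], NA_character_)
    top$constant <- is.na(top$r)
    lines <- c(lines,
               "| rank | gene | r | same cluster | clade | note |",
               "|---:|:---|---:|:---:|:---|:---|",
               vapply(seq_len(nrow(top)), function(i) sprintf(
                 "| %d | %s | %s | %s | %s | %s |",
                 top$rank[i], top$gene[i],
                 ifelse(is.na(top$r[i]), "NA", sprintf("%.3f", top$r[i])),
                 ifelse(is.na(top$same_cluster[i]), "-",
                        ifelse(top$same_cluster[i], "yes", "no")),
                 ifelse(is.na(top$clade[i]), "-", top$clade[i]),
                 ifelse(top$constant[i], "constant expression", "")), ""),
               "")
    tabs[[s]] <- cbind(sugar = s, top)
  }
  if (length(suspects))
    lines <- c(lines, "## Decoupling suspects", "",
               paste0("- ", suspects), "")
  list(markdown = lines,
       table = if (length(tabs)) do.call(rbind, tabs) else NULL,
       decoupling_suspects = suspects)
}
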