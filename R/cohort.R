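# Cohort-level error correction: correct a set of gene trees against one
# species tree and report the reconciliation-cost distribution before and
# after. This is the single-pass error-correction protocol (rounds = 1);
# unlimited rearrangement would simply converge the gene trees onto the
# species tree, so multi-round use is deliberate and opt-in.

hist_bins <- function(model) {
  if (model == "deepcoal")
    list(breaks = c(-0.5, 0.5, 1.5, 2.5, 3.5, 4.5, Inf),
         labels = c("0", "1", "2", "3", "4", ">4"))
  else
    # duplication-loss binning; also used for the duplication-only model
    list(breaks = c(-0.5, 0.5, 5.5, 10.5, 15.5, 20.5, Inf),
         labels = c("0", "1-5", "6-10", "11-15", "16-20", ">20"))
}

#' Histogram of reconciliation costs
#'
#' Bins a vector of integer costs with the conventional binning for the
#' model: `0,1,2,3,4,>4` for deep coalescence and `0,1-5,6-10,11-15,16-20,
#' >20` for duplication-loss (reused for duplication-only).
#'
#' @param costs Integer vector.
#' @param model One of `"dup"`, `"duploss"`, `"deepcoal"`.
#' @return A data frame with columns `bin` and `count`.
#' @export
cost_histogram <- function(costs, model) {
  model <- match.arg(model, COST_MODELS)
  b <- hist_bins(model)
  cut_ <- cut(costs, breaks = b$breaks, labels = b$labels)
  data.frame(bin = b$labels, count = as.integer(table(cut_)), row.names = NULL)
}

as_tree_input <- function(x, what) {
  if (inherits(x, "rbtree")) return(x)
  if (is.character(x) && length(x) == 1L) {
    trees <- read_newick_lines(x)
    if (length(trees) != 1L)
      stop(sprintf("expected a single %s tree in '%s', found %d", what, x,
                   length(trees)))
    return(trees[[1L]])
  }
  stop(sprintf("`%s` must be an rbtree or a file path", what))
}

as_gene_input <- function(x) {
  if (is.character(x) && length(x) == 1L) return(read_newick_lines(x))
  if (inherits(x, "rbtree")) return(list(x))
  if (is.list(x) && all(vapply(x, inherits, logical(1), "rbtree"))) return(x)
  stop("`genes` must be a file path, an rbtree, or a list of rbtrees")
}

#' Correct a cohort of gene trees against a species tree
#'
#' Applies [solve_sec()] (SPR) or [solve_tec()] (TBR) to each gene tree,
#' up to `rounds` times per gene (stopping as soon as no rearrangement
#' improves the cost), and summarizes the cost distribution before and
#' after correction. Each gene is reconciled against the species tree
#' restricted to the species it samples.
#'
#' @param species Species tree: an `rbtree` or a Newick file path.
#' @param genes Gene trees: a list of `rbtree`s or a path to a file with
#'   one Newick per line.
#' @param model One of `"dup"`, `"duploss"`, `"deepcoal"`.
#' @param neighborhood `"spr"` or `"tbr"`.
#' @param rounds Maximum correction passes per gene (default 1, the
#'   single-pass protocol; unlimited passes converge on the species tree).
#' @param species_delimiter Optional single character: gene leaf labels
#'   resolve to the prefix before its first occurrence.
#' @param root_with Optional species label: each gene tree is rerooted on
#'   the edge above the named (outgroup) leaf before correction.
#' @param verify If `TRUE`, every corrected gene is cross-checked against
#'   the naive neighborhood oracle (small trees only); a mismatch is an
#'   internal error, not a user error.
#' @param out_dir Optional directory; writes `corrected.nwk` (one Newick
#'   per line, input order), `report.tsv` and `summary.txt`.
#' @param quiet Suppress per-gene progress on stderr.
#' @return (Invisibly) a list with `report` (data frame: gene, n_leaves,
#'   n_species, original_cost, corrected_cost, edits_applied, edit),
#'   `trees` (corrected `rbtree`s), `histogram` (bin, original, corrected)
#'   and `summary` (character lines).
#' @examples
#' co <- make_cohort(n_taxa = 6, n_genes = 4)
#' res <- run_correct(co$species, co$genes, model = "deepcoal")
#' res$report
#' @export
run_correct <- function(species, genes, model = c("dup", "duploss", "deepcoal"),
                        neighborhood = c("spr", "tbr"), rounds = 1L,
                        species_delimiter = NULL, root_with = NULL,
                        verify = FALSE, out_dir = NULL, quiet = TRUE) {
  model <- match.arg(model)
  neighborhood <- match.arg(neighborhood)
  stopifnot(rounds >= 1L)
  s <- as_tree_input(species, "species")
  gs <- as_gene_input(genes)
  solver <- if (neighborhood == "spr") solve_sec else solve_tec

  n <- length(gs)
  out_trees <- vector("list", n)
  rep_rows <- vector("list", n)
  for (i in seq_len(n)) {
    g <- gs[[i]]
    if (!is.null(root_with)) {
      lv <- tree_leaves(g)
      hit <- lv[resolve_labels(g$label[lv], species_delimiter) == root_with]
      if (!length(hit))
        stop(sprintf("gene %d: outgroup label '%s' not found", i, root_with))
      g <- reroot(g, hit[1L])
    }
    orig <- tryCatch(
      reconciliation_cost(g, s, model, species_delimiter),
      error = function(e) stop(sprintf("gene %d: %s", i, conditionMessage(e)),
                               call. = FALSE))
    cur <- g
    cost <- orig
    applied <- 0L
    first_edit <- NULL
    for (r in seq_len(rounds)) {
      res <- solver(cur, s, model, species_delimiter)
      if (r == 1L && verify) {
        nb <- naive_best_in_neighborhood(g, s, model, move = neighborhood,
                                         species_delimiter = species_delimiter)
        if (res$best_cost != nb$best_cost)
          stop(sprintf(
            "internal error: gene %d solver minimum %d disagrees with oracle %d",
            i, res$best_cost, nb$best_cost))
      }
      if (is.null(res$edit)) break
      cur <- res$best_tree
      cost <- res$best_cost
      applied <- applied + 1L
      if (is.null(first_edit)) first_edit <- res$edit
    }
    ctx <- species_context(g, s, species_delimiter)
    rep_rows[[i]] <- data.frame(
      gene = i, n_leaves = n_leaves(g), n_species = n_leaves(ctx$s_eff),
      original_cost = orig, corrected_cost = cost, edits_applied = applied,
      edit = if (is.null(first_edit)) "none" else format(first_edit),
      stringsAsFactors = FALSE)
    out_trees[[i]] <- cur
    if (!quiet)
      message(sprintf("gene %d/%d: cost %d -> %d", i, n, orig, cost))
  }
  report <- do.call(rbind, rep_rows)

  hb <- cost_histogram(report$original_cost, model)
  ha <- cost_histogram(report$corrected_cost, model)
  histogram <- data.frame(bin = hb$bin, original = hb$count,
                          corrected = ha$count)
  summary_lines <- c(
    sprintf("Error correction: %d gene trees, %s cost, %s neighborhood, rounds=%d",
            n, model, neighborhood, rounds),
    sprintf("Total cost: %d -> %d",
            sum(report$original_cost), sum(report$corrected_cost)),
    "",
    sprintf("%-12s %9s %9s", "cost bin", "original", "corrected"),
    sprintf("%-12s %9d %9d", histogram$bin, histogram$original,
            histogram$corrected))

  result <- list(report = report, trees = out_trees, histogram = histogram,
                 summary = summary_lines)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_newick_lines(out_trees, file.path(out_dir, "corrected.nwk"))
    utils::write.table(report, file.path(out_dir, "report.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    writeLines(summary_lines, file.path(out_dir, "summary.txt"))
    result$paths <- c(corrected = file.path(out_dir, "corrected.nwk"),
                      report = file.path(out_dir, "report.tsv"),
                      summary = file.path(out_dir, "summary.txt"))
  }
  invisible(result)
}
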