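## End-to-end orchestration: measurements + tree -> species trait table,
## correlation matrix, per-trait signal/model report, PSR curves and
## traitgram coordinates, with input validation and deterministic outputs.

norm_species <- function(x) gsub("[ _]+", "_", trimws(as.character(x)))

#' Validate pipeline inputs without running the analysis
#'
#' Checks the measurement schema and geometric invariants (via
#' [validate_measurements()]), or a pre-aggregated species trait table, and
#' the tree (validity, ultrametricity — required by the OU fit), plus the
#' species overlap between the two. Diagnostics only; inputs are never
#' modified.
#'
#' @param tree A `phylo` object or path to a Newick file.
#' @param measurements Optional per-leaf measurement data frame or CSV path.
#' @param trait_table Optional `species_trait_table` (alternative input).
#' @return A data frame with columns `level` (`"error"`, `"warning"`,
#'   `"note"`), `context`, `message`; zero rows when everything is clean.
#' @export
validate_inputs <- function(tree, measurements = NULL, trait_table = NULL) {
  diags <- list()
  add <- function(level, context, message)
    diags[[length(diags) + 1L]] <<- data.frame(level = level,
                                               context = context,
                                               message = message)
  tree <- tryCatch({
    if (is.character(tree)) read_newick(tree) else validate_tree(tree)
  }, error = function(e) { add("error", "tree", conditionMessage(e)); NULL })
  if (!is.null(tree) && !is_ultrametric_tree(tree))
    add("warning", "tree",
        "tree is not ultrametric; the OU model fit requires a chronogram")
  species <- NULL
  if (!is.null(measurements)) {
    m <- tryCatch({
      if (is.character(measurements)) read_measurements(measurements)
      else measurements
    }, error = function(e) {
      add("error", "measurements", conditionMessage(e)); NULL
    })
    if (!is.null(m)) {
      pr <- validate_measurements(m)
      for (i in seq_len(nrow(pr)))
        add("error", "measurements",
            sprintf("row %d, %s: %s", pr$row[i], pr$field[i], pr$message[i]))
      species <- unique(norm_species(m$species))
    }
  }
  if (!is.null(trait_table)) {
    if (!inherits(trait_table, "species_trait_table"))
      add("error", "trait_table", "not a species_trait_table")
    else species <- unique(norm_species(trait_table$species))
  }
  if (!is.null(tree) && !is.null(species)) {
    shared <- intersect(norm_species(tree$tip.label), species)
    if (length(shared) < 4)
      add("error", "species",
          sprintf("only %d species shared between tree and data",
                  length(shared)))
    only_tree <- setdiff(norm_species(tree$tip.label), species)
    only_data <- setdiff(species, norm_species(tree$tip.label))
    if (length(only_tree))
      add("note", "species", paste("tips without trait data:",
                                   paste(only_tree, collapse = ", ")))
    if (length(only_data))
      add("note", "species", paste("species not in tree:",
                                   paste(only_data, collapse = ", ")))
  }
  if (!length(diags))
    return(data.frame(level = character(), context = character(),
                      message = character()))
  do.call(rbind, c(diags, list(make.row.names = FALSE)))
}

#' Run the full leaf-trait evolution analysis
#'
#' Executes the stages in order: derive per-leaf traits, aggregate to
#' species, Ln(x+1)-transform, trait correlations, per-trait phylogenetic
#' signal and BM/OU/WN comparison, PSR curves with a Monte-Carlo envelope,
#' and ancestral reconstruction / traitgram coordinates per trait. Species
#' names are matched after whitespace trimming and underscore/space
#' normalization; species present in only one input are pruned or dropped
#' and reported. Results are deterministic given the seed.
#'
#' @param tree A `phylo` object or Newick file path.
#' @param measurements Per-leaf measurement data frame or CSV path
#'   (exclusive with `trait_table`).
#' @param trait_table A raw-scale `species_trait_table` (alternative input).
#' @param agg Aggregation statistic: `"mean"` (the primary analysis),
#'   `"min"` or `"max"` (robustness runs).
#' @param transform Apply the Ln(x+1) transform before fitting (default
#'   `TRUE`).
#' @param envelope_model Generating model of the PSR envelope (`"WN"` or
#'   `"BM"`).
#' @param envelope_sims Number of envelope simulations.
#' @param seed Integer seed for the envelope simulations.
#' @param out_dir Optional directory; when given, all outputs are written
#'   there as CSV (full precision plus a 2-decimal display report) together
#'   with a run manifest.
#' @param verbose Emit progress messages.
#' @return A `leafevo_run` list: `species_traits`, `correlations`, `report`
#'   (full precision), `report_display`, `psr_curves` (long data frame),
#'   `psr_areas`, `envelope`, `traitgrams` (named list), `dropped`
#'   (species reconciliation info), `settings`.
#' @export
run_full_analysis <- function(tree, measurements = NULL, trait_table = NULL,
                              agg = c("mean", "min", "max"),
                              transform = TRUE,
                              envelope_model = c("WN", "BM"),
                              envelope_sims = 199L, seed = 1L,
                              out_dir = NULL, verbose = FALSE) {
  agg <- match.arg(agg)
  envelope_model <- match.arg(envelope_model)
  say <- function(...) if (verbose) message(...)
  if (is.character(tree)) tree <- read_newick(tree)
  validate_tree(tree)
  if (is.null(measurements) == is.null(trait_table))
    stop("supply exactly one of 'measurements' or 'trait_table'",
         call. = FALSE)
  if (!is.null(measurements)) {
    if (is.character(measurements))
      measurements <- read_measurements(measurements)
    say("deriving per-leaf traits for ", nrow(measurements), " leaves")
    leaf <- derive_traits(measurements)
    leaf$species <- norm_species(leaf$species)
    table <- aggregate_species(leaf, stat = agg)
  } else {
    if (!inherits(trait_table, "species_trait_table"))
      stop("'trait_table' must come from aggregate_species()", call. = FALSE)
    table <- trait_table
    table$species <- norm_species(table$species)
  }
  tree$tip.label <- norm_species(tree$tip.label)
  shared <- intersect(table$species, tree$tip.label)
  dropped <- list(tips_pruned = setdiff(tree$tip.label, shared),
                  species_dropped = setdiff(table$species, shared))
  if (length(shared) < 4)
    stop("fewer than 4 species shared between tree and data", call. = FALSE)
  if (length(dropped$tips_pruned))
    say("pruning ", length(dropped$tips_pruned), " tip(s) without data: ",
        paste(dropped$tips_pruned, collapse = ", "))
  if (length(dropped$species_dropped))
    say("dropping ", length(dropped$species_dropped),
        " species not in tree: ",
        paste(dropped$species_dropped, collapse = ", "))
  tree <- prune_to(tree, shared)
  table <- table[table$species %in% shared, , drop = FALSE]
  if (transform) table <- ln1p_transform(table)
  say("computing trait correlations")
  correlations <- trait_correlations(table)
  say("fitting signal and evolutionary models for ",
      length(trait_names()), " traits")
  report <- signal_report(table, tree)
  say("building PSR curves")
  basis <- phylo_eigenbasis(patristic_matrix(tree))
  curves <- list(); areas <- numeric(0)
  for (tr in report$trait) {
    x <- stats::setNames(table[[tr]], table$species)
    cv <- psr_curve(x, basis)
    curves[[tr]] <- cbind(trait = tr, cv$points)
    areas[tr] <- cv$area
  }
  envelope <- psr_envelope(tree, model = envelope_model,
                           n_sims = envelope_sims, seed = seed)
  say("reconstructing ancestral states")
  traitgrams <- lapply(stats::setNames(report$trait, report$trait),
                       function(tr) {
    x <- stats::setNames(table[[tr]], table$species)
    traitgram_data(tree, x)
  })
  out <- structure(list(
    species_traits = table,
    correlations = correlations,
    report = report,
    report_display = format_signal_report(report),
    psr_curves = do.call(rbind, c(curves, list(make.row.names = FALSE))),
    psr_areas = areas,
    envelope = envelope,
    traitgrams = traitgrams,
    dropped = dropped,
    settings = list(agg = agg, transform = transform,
                    envelope_model = envelope_model,
                    envelope_sims = envelope_sims, seed = seed,
                    n_species = length(shared))),
    class = "leafevo_run")
  if (!is.null(out_dir)) write_run(out, tree, out_dir)
  out
}

write_run <- function(run, tree, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  write.csv(as.data.frame(run$species_traits), p("species_traits.csv"),
            row.names = FALSE)
  write_matrix_csv(run$correlations, p("trait_correlations.csv"))
  write.csv(as.data.frame(run$report), p("signal_report_full.csv"),
            row.names = FALSE)
  write.csv(run$report_display, p("signal_report.csv"), row.names = FALSE)
  write.csv(run$psr_curves, p("psr_curves.csv"), row.names = FALSE)
  write.csv(run$envelope$band, p("psr_envelope.csv"), row.names = FALSE)
  write_newick(tree, p("pruned_tree.nwk"))
  for (tr in names(run$traitgrams))
    write.csv(as.data.frame(run$traitgrams[[tr]]$nodes),
              p(sprintf("traitgram_%s.csv", tr)), row.names = FALSE)
  manifest <- c(
    sprintf("aggregation: %s", run$settings$agg),
    sprintf("transform: %s",
            if (run$settings$transform) "ln1p" else "raw"),
    sprintf("envelope_model: %s", run$settings$envelope_model),
    sprintf("envelope_sims: %d", run$settings$envelope_sims),
    sprintf("seed: %s", format(run$settings$seed)),
    sprintf("n_species: %d", run$settings$n_species),
    sprintf("tips_pruned: %s",
            paste(run$dropped$tips_pruned, collapse = " ")),
    sprintf("species_dropped: %s",
            paste(run$dropped$species_dropped, collapse = " ")))
  writeLines(manifest, p("run_manifest.txt"))
  invisible(out_dir)
}

#' @export
print.leafevo_run <- function(x, ...) {
  cat(sprintf("leaf-trait evolution analysis: %d species, %d traits fitted\n",
              x$settings$n_species, nrow(x$report)))
  cat(sprintf("  aggregation = %s, transform = %s, envelope = %s (%d sims)\n",
              x$settings$agg,
              if (x$settings$transform) "ln1p" else "raw",
              x$settings$envelope_model, x$settings$envelope_sims))
  print(x$report_display)
  invisible(x)
}
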