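# End-to-end driver: curation summary, phylogenetic-signal tests on %mC
# (all species) and on C-value (complete cases), paired independent
# contrasts on the complete-case subtree, and the permutation-tested
# through-origin regression, assembled into one machine-readable report.

#' Run the full comparative analysis
#'
#' Executes the whole workflow on a tree and a species-level trait
#' table: validates that species match tree tips exactly, optionally sets
#' unit branch lengths and resolves polytomies (seeded), runs the four
#' phylogenetic-signal randomization tests on %mC (all species) and on
#' the genome-size trait (complete cases only), computes paired
#' independent contrasts of %mC and log10 C-value on the complete-case
#' subtree, tests both contrast sets for normality, fits the
#' through-origin regression with its permutation test, and collects
#' diagnostics. No species is ever dropped silently: every exclusion is
#' listed in the curation section with its reason.
#'
#' @param tree a rooted `"phylo"` object whose tip labels match
#'   `traits$species` exactly.
#' @param traits species-level data frame (see [read_species_table()])
#'   with columns `species`, `percent_mC` and (optionally incomplete)
#'   `c_value_pg`.
#' @param n_reps randomization replicates for Moran's I, Abouheif's
#'   Cmean and Blomberg's K, and for the regression permutation test.
#' @param n_reps_lambda randomization replicates for Pagel's lambda
#'   (the statistic re-estimated per permutation is an ML fit, so its
#'   default is lower).
#' @param seed master seed; each stochastic stage uses a fixed offset of
#'   it, recorded in the report.
#' @param unit_branch_lengths set all branch lengths to 1 first?
#' @param log_cvalue_signal run the signal tests on log10-transformed
#'   C-values instead of raw C-values (contrasts always use log10).
#' @return a list of class `"methyl_report"` with elements `curation`,
#'   `signal` (per trait, one `"signal_result"` per index), `contrasts`,
#'   `regression`, `diagnostics`, `seeds`, `version`.
#' @export
run_full_analysis <- function(tree, traits,
                              n_reps = 100000, n_reps_lambda = 999,
                              seed = 1, unit_branch_lengths = TRUE,
                              log_cvalue_signal = FALSE) {
  if (is.null(traits$species)) stop("traits need a 'species' column")
  if (is.null(traits$percent_mC)) stop("traits need a 'percent_mC' column")
  validate_phylo(tree)
  only_tree <- setdiff(tree$tip.label, traits$species)
  only_traits <- setdiff(traits$species, tree$tip.label)
  if (length(only_tree) || length(only_traits))
    stop("species/tip mismatch.\n  in tree only: ",
         paste(only_tree, collapse = ", "),
         "\n  in traits only: ", paste(only_traits, collapse = ", "))

  if (unit_branch_lengths || is.null(tree$edge.length))
    tree <- set_unit_branch_lengths(tree)
  resolved <- !tree_is_binary(tree)
  tree <- resolve_polytomies(tree, seed = seed)

  mc <- setNames(traits$percent_mC, traits$species)
  if (anyNA(mc)) stop("percent_mC has missing values for: ",
                      paste(names(mc)[is.na(mc)], collapse = ", "))
  cval <- if (!is.null(traits$c_value_pg))
    setNames(traits$c_value_pg, traits$species) else
    setNames(rep(NA_real_, nrow(traits)), traits$species)
  complete <- names(cval)[!is.na(cval)]
  if (length(complete) < 3L)
    stop("fewer than 3 species have complete trait data")

  indices <- c("morans_I", "abouheif_Cmean", "blomberg_K", "pagel_lambda")
  seeds <- list(resolve = seed,
                signal_mc = seed + 101L, signal_cvalue = seed + 202L,
                permutation = seed + 303L)

  signal_for <- function(tr, x, base_seed) {
    res <- lapply(seq_along(indices), function(k) {
      reps <- if (indices[k] == "pagel_lambda") n_reps_lambda else n_reps
      randomization_test(tr, x, index = indices[k], n_reps = reps,
                         seed = base_seed + k)
    })
    names(res) <- indices
    res
  }
  signal_mc <- signal_for(tree, mc, seeds$signal_mc)

  sub <- prune_to_taxa(tree, complete)
  cv_for_signal <- if (log_cvalue_signal) log10_transform(cval[complete])
                   else cval[complete]
  signal_cv <- signal_for(sub, cv_for_signal, seeds$signal_cvalue)

  pic_mc <- pic_contrasts(sub, mc[complete])
  pic_logc <- pic_contrasts(sub, log10_transform(cval[complete]))
  stopifnot(identical(pic_mc$node, pic_logc$node))
  fit <- origin_regression(pic_logc, pic_mc)
  permu <- origin_permutation_test(pic_logc, pic_mc, n_reps = n_reps,
                                   seed = seeds$permutation)
  diag <- regression_diagnostics(fit)

  curation <- list(
    n_species = length(mc),
    n_complete = length(complete),
    excluded_from_regression = setNames(
      rep("missing C-value", length(mc) - length(complete)),
      setdiff(names(mc), complete)),
    polytomies_resolved = resolved,
    mc_summary = list(mean = mean(mc), sd = sd(mc),
                      min = min(mc), max = max(mc))
  )

  structure(list(
    curation = curation,
    signal = list(percent_mC = signal_mc, c_value = signal_cv),
    cvalue_signal_scale = if (log_cvalue_signal) "log10" else "raw",
    contrasts = list(percent_mC = pic_mc, log10_c_value = pic_logc,
                     normality = list(
                       percent_mC = shapiro_wilk(pic_mc),
                       log10_c_value = shapiro_wilk(pic_logc))),
    regression = fit,
    permutation = permu,
    diagnostics = diag,
    seeds = seeds,
    n_reps = list(autocorrelation = n_reps, lambda = n_reps_lambda,
                  permutation = n_reps),
    version = as.character(packageVersion("phylomethyl"))
  ), class = "methyl_report")
}

#' @export
print.methyl_report <- function(x, ...) {
  cat("Phylogenetic analysis of global cytosine methylation\n")
  cat(sprintf("  %d species (%d with C-values); %%mC mean %.1f, range %.1f-%.1f\n",
              x$curation$n_species, x$curation$n_complete,
              x$curation$mc_summary$mean, x$curation$mc_summary$min,
              x$curation$mc_summary$max))
  cat("Signal, %mC:\n")
  for (r in x$signal$percent_mC) { cat("  "); print(r) }
  cat(sprintf("Signal, C-value (%s scale):\n", x$cvalue_signal_scale))
  for (r in x$signal$c_value) { cat("  "); print(r) }
  cat(sprintf("Contrast normality: W = %.3f (%%mC), %.3f (log10 C-value)\n",
              x$contrasts$normality$percent_mC$W,
              x$contrasts$normality$log10_c_value$W))
  print(x$regression)
  print(x$permutation)
  print(x$diagnostics)
  invisible(x)
}

#' Serialize an analysis report to JSON
#'
#' Writes the report (minus bulky residual tables) as JSON with
#' unboxed scalars, suitable for machine consumption.
#'
#' @param report a `"methyl_report"`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  if (!inherits(report, "methyl_report")) stop("not a methyl_report")
  strip <- function(r) {
    r$diagnostics$table <- NULL
    r$regression$residuals <- NULL
    r$regression$fitted <- NULL
    unclass_deep(r)
  }
  jsonlite::write_json(strip(report), path, auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  invisible(path)
}

unclass_deep <- function(x) {
  if (is.data.frame(x)) return(x)
  if (is.list(x)) return(lapply(unclass(x), unclass_deep))
  x
}
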