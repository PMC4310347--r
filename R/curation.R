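# Trait curation: %mC from HPLC peak areas, filtering and averaging
# rules that turn heterogeneous per-sample estimates (own lab + published
# values) into one mean %mC per species, and trait-table I/O.

#' Global cytosine methylation from HPLC peak areas
#'
#' The percent of genomic cytosines that are methylated is estimated per
#' sample as \deqn{100 \times 5mdC / (5mdC + dC)} where `5mdC` and `dC`
#' are the integrated chromatogram peak areas of
#' 5-methyl-2'-deoxycytidine and 2'-deoxycytidine. The result is
#' invariant to the (arbitrary) area units: scaling both areas by the
#' same positive constant leaves it unchanged.
#'
#' @param area_5mdC,area_dC non-negative peak areas (vectorized).
#' @return percent methylation in `[0, 100]`.
#' @examples
#' percent_methylation(1, 3)   # 25
#' @export
percent_methylation <- function(area_5mdC, area_dC) {
  if (any(area_5mdC < 0, na.rm = TRUE) || any(area_dC < 0, na.rm = TRUE))
    stop("peak areas must be non-negative")
  tot <- area_5mdC + area_dC
  if (any(tot == 0, na.rm = TRUE))
    stop("both peak areas are zero: no signal")
  100 * area_5mdC / tot
}

#' Read a sample-level methylation table
#'
#' CSV with one row per measured sample. Required columns: `species`,
#' `source` (`lab`/`literature`), `treatment` (`control`/`treated`/
#' `unknown`). Optional: `tissue`, `genotype`, `area_5mdC`, `area_dC`,
#' `percent_mC`. Each row must carry either both peak areas or a
#' precomputed `percent_mC`. UTF-8, header row, `.` decimal separator.
#'
#' @param path path to the CSV file.
#' @return a data frame of samples.
#' @export
read_sample_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  need <- c("species", "source", "treatment")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("sample table missing columns: ", paste(miss, collapse = ", "))
  if (is.null(df$percent_mC)) df$percent_mC <- NA_real_
  has_area <- !is.null(df$area_5mdC) && !is.null(df$area_dC)
  ok <- !is.na(df$percent_mC) |
    (has_area & !is.na(df$area_5mdC) & !is.na(df$area_dC))
  if (any(!ok))
    stop("rows without peak areas or percent_mC: ",
         paste(which(!ok), collapse = ", "))
  bad <- !is.na(df$percent_mC) & (df$percent_mC < 0 | df$percent_mC > 100)
  if (any(bad))
    stop("percent_mC outside [0, 100] in rows: ",
         paste(which(bad), collapse = ", "))
  df
}

#' Aggregate methylation samples into species means
#'
#' Applies the curation rules for combining lab and literature estimates
#' of %mC into a single species-level table:
#' \enumerate{
#'   \item rows whose `tissue` is stated and is not `"leaf"` are dropped
#'     (plant parts differ in methylation level; absent/empty tissue is
#'     treated as leaf);
#'   \item rows with `treatment == "treated"` are dropped — only control
#'     values from experimental studies are used (`unknown` is kept);
#'   \item missing `percent_mC` is filled from the peak areas with
#'     [percent_methylation()];
#'   \item when a `genotype` column is present, samples are first
#'     averaged within species x source x genotype, so multi-genotype
#'     studies contribute one value per genotype;
#'   \item a mean per species and source (`lab` / `literature`) is
#'     computed, and finally one mean per species.
#' }
#' When a species has estimates from both sources, the default
#' (`source_combine = "equal"`) averages the two source means with equal
#' weight; `"pooled"` averages all (genotype-averaged) values regardless
#' of source.
#'
#' Species with no surviving samples after filtering are excluded with a
#' warning.
#'
#' @param samples data frame as returned by [read_sample_table()].
#' @param source_combine `"equal"` or `"pooled"` (see Details).
#' @return a data frame with columns `species`, `percent_mC`,
#'   `n_replicates` (surviving raw samples) and `n_sources`.
#' @export
aggregate_species_means <- function(samples,
                                    source_combine = c("equal", "pooled")) {
  source_combine <- match.arg(source_combine)
  if (!nrow(samples)) stop("empty sample table")
  df <- samples
  if (is.null(df$percent_mC)) df$percent_mC <- NA_real_
  fill <- is.na(df$percent_mC)
  if (any(fill)) {
    if (is.null(df$area_5mdC) || is.null(df$area_dC))
      stop("rows lack percent_mC and no peak-area columns are present")
    df$percent_mC[fill] <- percent_methylation(df$area_5mdC[fill],
                                               df$area_dC[fill])
  }
  keep <- rep(TRUE, nrow(df))
  if (!is.null(df$tissue)) {
    tis <- trimws(tolower(as.character(df$tissue)))
    keep <- keep & (is.na(tis) | tis == "" | tis == "leaf")
  }
  trt <- trimws(tolower(as.character(df$treatment)))
  keep <- keep & !(trt %in% "treated")

  lost <- setdiff(unique(df$species), unique(df$species[keep]))
  if (length(lost))
    warning("species excluded (no surviving samples): ",
            paste(lost, collapse = ", "))
  df <- df[keep, , drop = FALSE]
  if (!nrow(df)) stop("no samples survive the curation filters")

  # without genotype information every sample is its own unit, so the
  # pooled combine averages raw samples rather than source means
  geno <- if (!is.null(df$genotype)) as.character(df$genotype)
          else as.character(seq_len(nrow(df)))
  geno[is.na(geno)] <- ""
  # within species x source x genotype
  g1 <- aggregate(df$percent_mC,
                  by = list(species = df$species, source = df$source,
                            genotype = geno),
                  FUN = mean)
  # source means (one value per genotype each)
  g2 <- aggregate(g1$x,
                  by = list(species = g1$species, source = g1$source),
                  FUN = mean)
  if (source_combine == "equal") {
    sp <- aggregate(g2$x, by = list(species = g2$species), FUN = mean)
  } else {
    sp <- aggregate(g1$x, by = list(species = g1$species), FUN = mean)
  }
  nrep <- table(df$species)
  nsrc <- table(unique(g2[c("species", "source")])$species)
  out <- data.frame(species = sp$species,
                    percent_mC = sp$x,
                    n_replicates = as.integer(nrep[sp$species]),
                    n_sources = as.integer(nsrc[sp$species]),
                    stringsAsFactors = FALSE)
  out[order(out$species), , drop = FALSE]
}

#' One-way variance-partition ANOVA
#'
#' Fixed-effects one-way ANOVA used to partition %mC variance, e.g.
#' between data sources (lab vs. literature) or among vs. within species
#' for the replicated subset. Returns the F statistic with its degrees of
#' freedom and the adjusted R-squared
#' \eqn{1 - (SS_w/(n-k)) / (SS_t/(n-1))}.
#'
#' @param values numeric response vector.
#' @param groups group labels, same length as `values`.
#' @return a list with `F`, `df1`, `df2`, `p_value`, `adj_r_squared`.
#' @export
variance_partition_anova <- function(values, groups) {
  if (length(values) != length(groups))
    stop("'values' and 'groups' lengths differ")
  groups <- factor(groups)
  k <- nlevels(groups)
  n <- length(values)
  if (k < 2L) stop("need at least 2 groups")
  if (n <= k) stop("need more observations than groups")
  fit <- lm(values ~ groups)
  if (sum(fit$residuals^2) <= .Machine$double.eps * sum(values^2) * n)
    stop("zero within-group variance: F is undefined")
  a <- anova(fit)
  list(F = a[["F value"]][1L],
       df1 = a[["Df"]][1L],
       df2 = a[["Df"]][2L],
       p_value = a[["Pr(>F)"]][1L],
       adj_r_squared = summary(fit)$adj.r.squared)
}

#' Read / write a species-level trait table
#'
#' Species-level CSV with columns `species` (required), `family`,
#' `percent_mC`, `c_value_pg` (haploid genome size in picograms; may be
#' missing for some species and is never imputed) and `n_replicates`.
#' Unknown columns are preserved but ignored by the analyses.
#'
#' @param path path to the CSV file.
#' @return `read_species_table()`: a data frame with one row per species.
#' @export
read_species_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  if (is.null(df$species)) stop("species table needs a 'species' column")
  if (anyDuplicated(df$species))
    stop("duplicate species rows: ",
         paste(unique(df$species[duplicated(df$species)]), collapse = ", "))
  if (!is.null(df$percent_mC)) {
    bad <- !is.na(df$percent_mC) & (df$percent_mC < 0 | df$percent_mC > 100)
    if (any(bad))
      stop("percent_mC outside [0, 100] for: ",
           paste(df$species[bad], collapse = ", "))
  }
  if (!is.null(df$c_value_pg)) {
    bad <- !is.na(df$c_value_pg) & df$c_value_pg <= 0
    if (any(bad))
      stop("non-positive c_value_pg for: ",
           paste(df$species[bad], collapse = ", "))
  }
  df
}

#' @rdname read_species_table
#' @param table a species-level data frame.
#' @export
write_species_table <- function(table, path) {
  write.csv(table, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
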