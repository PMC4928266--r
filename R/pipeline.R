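# End-to-end orchestration: ingest or simulate a study, run every analysis
# stage in order, and emit a reproducible bundle of labelled CSV tables plus
# a JSON provenance file.

#' Configure a pipeline run
#'
#' Exactly one of `study` (an in-memory `parid_study`, typically from
#' [generate_study()]) or `input_dir` (a directory of exchange files readable
#' by [read_study()]) must be given.
#'
#' @param study a `parid_study`, or `NULL`.
#' @param input_dir directory of input files, or `NULL`.
#' @param output_dir where to write the report bundle; `NULL` returns tables
#'   without writing.
#' @param seed master seed for the stochastic stages (permutation tests).
#' @param exclude_species optional species to drop in a second run of the
#'   signal and Mantel stages (the with/without-outlier comparison).
#' @param intraspecific_species species used for the within-species altitude
#'   regressions; default: the species with the widest altitudinal interval.
#' @param n_perm_mantel Mantel permutations (default 10000).
#' @param n_perm_signal permutations for the Blomberg K test.
#' @param phylomorphospace_axes shape PC axes to project the tree onto.
#' @return list of class `parid_pipeline_config`.
#' @export
pipeline_config <- function(study = NULL, input_dir = NULL, output_dir = NULL,
                            seed = 1L, exclude_species = NULL,
                            intraspecific_species = NULL,
                            n_perm_mantel = 10000L, n_perm_signal = 999L,
                            phylomorphospace_axes = c("PC1", "PC2")) {
  if (is.null(study) == is.null(input_dir)) {
    abort("give exactly one of `study` or `input_dir`")
  }
  structure(
    list(study = study, input_dir = input_dir, output_dir = output_dir,
         seed = as.integer(seed), exclude_species = exclude_species,
         intraspecific_species = intraspecific_species,
         n_perm_mantel = as.integer(n_perm_mantel),
         n_perm_signal = as.integer(n_perm_signal),
         phylomorphospace_axes = phylomorphospace_axes),
    class = "parid_pipeline_config"
  )
}

#' @keywords internal
stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  })
}

#' @keywords internal
dist_to_csv <- function(d) {
  dplyr::bind_cols(tibble::tibble(species = rownames(d)), tibble::as_tibble(d))
}

#' Run the full analysis pipeline
#'
#' Stages, in order: per-trait one-way ANOVAs on log traits; body CVA over
#' all complete individuals (Mahalanobis matrix); body PCA on standardized
#' species means; GPA with sliding semilandmarks; Procrustes ANOVA (shape and
#' size); shape CVA; shape PCA on species mean shapes; phylomorphospace;
#' phylogenetic-signal table (log traits, size-corrected traits, body and
#' shape PC scores), optionally re-run without an excluded species;
#' interspecific PGLS of each trait on altitudinal midpoints plus
#' intraspecific OLS within the designated wide-ranging species; and partial
#' Mantel tests of {body, beak} Mahalanobis distances against {geographic,
#' altitudinal} overlap distances, controlling for phylogenetic distance.
#'
#' @param config a `parid_pipeline_config`.
#' @return object of class `parid_report`: named list of tibbles (and
#'   distance matrices), with attribute `paths` when written to disk.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "parid_pipeline_config"))
  study <- config$study %||% read_study(config$input_dir)
  seeds <- derive_seeds(config$seed, 4L)
  tree <- study$tree
  meas <- study$measurements
  lms <- study$landmarks

  # species consistency across inputs
  stage("consistency", {
    bad <- setdiff(unique(meas$species), tree$tip.label)
    if (length(bad) > 0L) abort(paste0("species absent from the tree: ", paste(bad, collapse = ", ")))
    bad_lm <- setdiff(unique(lms$species), c(tree$tip.label, NA))
    if (length(bad_lm) > 0L) abort(paste0("landmark species absent from the tree: ", paste(bad_lm, collapse = ", ")))
    bad_rg <- setdiff(tree$tip.label, study$ranges$species)
    if (length(bad_rg) > 0L) abort(paste0("tree tips without range records: ", paste(bad_rg, collapse = ", ")))
  })

  logm <- stage("log_transform", log_transform(meas))
  traits <- intersect(trait_names(), names(logm))

  anova_table <- stage("trait_anova", purrr::map_dfr(traits, function(v) {
    dplyr::mutate(tidy(one_way_anova(logm, v, "species")), trait = v, .before = 1L)
  }))

  body_cva <- stage("body_cva", morpho_cva(logm[, c("species", traits)], "species"))

  body_means <- stage("species_means", species_means(logm[, c("species", traits)]))
  body_pca <- stage("body_pca", morpho_pca(standardize(body_means), mode = "covariance"))

  aligned <- stage("gpa", slide_semilandmarks(gpa(lms)))
  tang <- stage("tangent", tangent_project(aligned))

  panova <- stage("procrustes_anova", procrustes_anova(tang))

  shape_cva <- stage("shape_cva", morpho_cva(tangent_matrix(tang), tang$species))

  shape_mean_tbl <- stage("shape_means", {
    sm <- species_means(dplyr::select(tang, -"centroid_size", -"specimen_id"))
    sm
  })
  shape_pca <- stage("shape_pca", morpho_pca(shape_mean_tbl, mode = "covariance"))

  pms <- stage("phylomorphospace", {
    sc <- shape_pca$scores
    phylomorphospace(tree, sc, axes = intersect(config$phylomorphospace_axes, names(sc)))
  })

  # species-level trait tables for the comparative stages
  sc_body <- body_pca$scores
  names(sc_body)[names(sc_body) != "species"] <- paste0("body_", setdiff(names(sc_body), "species"))
  sc_shape <- shape_pca$scores
  keep_pcs <- intersect(paste0("PC", 1:3), names(sc_shape))
  sc_shape <- sc_shape[, c("species", keep_pcs)]
  names(sc_shape)[names(sc_shape) != "species"] <- paste0("beak_", keep_pcs)
  size_corr <- stage("size_correct", size_correct(body_means))
  names(size_corr)[names(size_corr) != "species"] <-
    paste0("sc_", setdiff(names(size_corr), "species"))
  signal_data <- body_means |>
    dplyr::left_join(size_corr, by = "species") |>
    dplyr::left_join(sc_body[, c("species", intersect(c("body_PC1", "body_PC2"), names(sc_body)))],
                     by = "species") |>
    dplyr::left_join(sc_shape, by = "species")

  signal <- stage("phylogenetic_signal", {
    out <- dplyr::mutate(
      signal_table(tree, signal_data, n_perm = config$n_perm_signal, seed = seeds[[1L]]),
      subset = "all", .before = 1L)
    if (!is.null(config$exclude_species)) {
      keep <- setdiff(tree$tip.label, config$exclude_species)
      tr2 <- ape::keep.tip(tree, keep)
      d2 <- signal_data[signal_data$species %in% keep, ]
      out <- dplyr::bind_rows(out, dplyr::mutate(
        signal_table(tr2, d2, n_perm = config$n_perm_signal, seed = seeds[[2L]]),
        subset = paste0("without_", paste(config$exclude_species, collapse = "+")), .before = 1L))
    }
    out
  })

  regressions <- stage("altitude_regressions", {
    mid <- study$ranges |>
      dplyr::mutate(alt_mid = (.data$alt_min + .data$alt_max) / 2) |>
      dplyr::select("species", "alt_mid")
    inter_data <- dplyr::left_join(signal_data, mid, by = "species")
    inter <- purrr::map_dfr(setdiff(names(signal_data), "species"), function(v) {
      dplyr::mutate(tidy(pgls(inter_data, v, "alt_mid", tree)),
                    trait = v, level = "interspecific_pgls", .before = 1L)
    })
    focal <- config$intraspecific_species %||% {
      spans <- study$ranges$alt_max - study$ranges$alt_min
      study$ranges$species[[which.max(spans)]]
    }
    within <- logm[logm$species == focal & !is.na(logm$altitude), ]
    intra <- NULL
    if (nrow(within) >= 3L && sd(within$altitude) > 0) {
      intra <- purrr::map_dfr(traits, function(v) {
        dplyr::mutate(ols_regression(within, v, "altitude"),
                      trait = v, level = paste0("intraspecific_ols_", focal), .before = 1L)
      })
    }
    dplyr::bind_rows(inter, intra)
  })

  mantel <- stage("partial_mantel", {
    d_geo <- overlap_distance_matrix(study$ranges, study$overlaps)
    d_alt <- altitudinal_overlap_distance(study$ranges)
    d_phy <- phylogenetic_distance_matrix(tree)
    combos <- tidyr::expand_grid(
      morphology = c("body", "beak"),
      distribution = c("geographic", "altitudinal")
    )
    ord <- study$ranges$species
    morpho <- list(
      body = body_cva$mahalanobis[ord, ord],
      beak = shape_cva$mahalanobis[ord, ord]
    )
    distr <- list(geographic = d_geo[ord, ord], altitudinal = d_alt[ord, ord])
    purrr::pmap_dfr(combos, function(morphology, distribution) {
      res <- partial_mantel(morpho[[morphology]], distr[[distribution]],
                            d_phy[ord, ord], n_perm = config$n_perm_mantel,
                            seed = seeds[[3L]])
      dplyr::mutate(tidy(res), morphology = morphology,
                    distribution = distribution, .before = 1L)
    })
  })

  report <- structure(
    list(
      anova = anova_table,
      body_mahalanobis = body_cva$mahalanobis,
      body_pca_scores = body_pca$scores,
      body_pca_loadings = dplyr::bind_cols(tibble::tibble(trait = rownames(body_pca$loadings)),
                                           tibble::as_tibble(body_pca$loadings)),
      body_pca_variance = glance(body_pca),
      aligned_shapes = tidy(aligned),
      procrustes_anova = tidy(panova),
      shape_mahalanobis = shape_cva$mahalanobis,
      shape_pca_scores = shape_pca$scores,
      shape_pca_variance = glance(shape_pca),
      phylomorphospace_nodes = pms$nodes,
      phylomorphospace_edges = pms$edges,
      signal = signal,
      regressions = regressions,
      mantel = mantel
    ),
    class = "parid_report"
  )
  attr(report, "gpa") <- aligned
  attr(report, "study") <- study

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- character(0)
    for (nm in names(report)) {
      obj <- report[[nm]]
      tbl <- if (is.matrix(obj)) dist_to_csv(obj) else obj
      p <- file.path(config$output_dir, paste0(nm, ".csv"))
      readr::write_csv(tbl, p)
      paths[[nm]] <- p
    }
    prov <- list(
      seed = config$seed, stage_seeds = seeds,
      n_perm_mantel = config$n_perm_mantel, n_perm_signal = config$n_perm_signal,
      exclude_species = config$exclude_species,
      n_species = length(tree$tip.label),
      n_measurements = nrow(meas),
      n_configurations = dplyr::n_distinct(lms$specimen_id),
      package_version = as.character(utils::packageVersion("paridmorph")),
      r_version = paste(R.version$major, R.version$minor, sep = ".")
    )
    pp <- file.path(config$output_dir, "provenance.json")
    jsonlite::write_json(prov, pp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    paths[["provenance"]] <- pp
    attr(report, "paths") <- paths
  }
  report
}

#' @export
print.parid_report <- function(x, ...) {
  cat("Pipeline report with tables:\n ", paste(names(x), collapse = ", "), "\n")
  invisible(x)
}

#' One-page summary of a report bundle
#'
#' @param report a `parid_report`, or a directory containing the CSV bundle.
#' @return character vector of summary lines, invisibly; printed as a side
#'   effect.
#' @export
describe_report <- function(report) {
  if (is.character(report)) {
    dir <- report
    if (!dir.exists(dir) || length(list.files(dir, pattern = "\\.csv$")) == 0L) {
      abort(sprintf("no report tables found in '%s'", dir))
    }
    read1 <- function(nm) {
      p <- file.path(dir, paste0(nm, ".csv"))
      if (file.exists(p)) readr::read_csv(p, show_col_types = FALSE, progress = FALSE) else NULL
    }
    report <- list(
      anova = read1("anova"), body_pca_variance = read1("body_pca_variance"),
      shape_pca_variance = read1("shape_pca_variance"),
      procrustes_anova = read1("procrustes_anova"),
      signal = read1("signal"), regressions = read1("regressions"),
      mantel = read1("mantel")
    )
  }
  lines <- character(0)
  say <- function(...) lines <<- c(lines, sprintf(...))
  miss <- function(nm) { warn(sprintf("table '%s' missing; partial summary", nm)) }
  if (!is.null(report$anova)) {
    say("Trait ANOVAs: F range %.3g - %.3g (all df_between = %d)",
        min(report$anova$F), max(report$anova$F), report$anova$df_between[[1L]])
  } else miss("anova")
  if (!is.null(report$body_pca_variance)) {
    v <- report$body_pca_variance$variance_fraction
    say("Body PCA: PC1 %.2f%%, PC2 %.2f%% of variance", 100 * v[[1L]], 100 * v[[2L]])
  } else miss("body_pca_variance")
  if (!is.null(report$shape_pca_variance)) {
    v <- report$shape_pca_variance$variance_fraction
    say("Shape PCA: first 3 PCs carry %.2f%% of variance", 100 * sum(head(v, 3L)))
  } else miss("shape_pca_variance")
  if (!is.null(report$procrustes_anova)) {
    sh <- report$procrustes_anova[report$procrustes_anova$effect == "shape", ]
    sz <- report$procrustes_anova[report$procrustes_anova$effect == "size", ]
    say("Procrustes ANOVA: shape F(%d, %d) = %.4g, p = %.3g", sh$df_between, sh$df_within, sh$F, sh$p)
    if (nrow(sz) > 0L) say("                  size  F(%d, %d) = %.4g, p = %.3g", sz$df_between, sz$df_within, sz$F, sz$p)
  } else miss("procrustes_anova")
  if (!is.null(report$signal)) {
    sig <- report$signal[report$signal$p < 0.05, ]
    say("Phylogenetic signal: %d of %d tests significant at 0.05", nrow(sig), nrow(report$signal))
  } else miss("signal")
  if (!is.null(report$regressions)) {
    say("Altitude regressions: %d fits (%d with p < 0.05)",
        nrow(report$regressions), sum(report$regressions$p < 0.05))
  } else miss("regressions")
  if (!is.null(report$mantel)) {
    for (r in seq_len(nrow(report$mantel))) {
      say("Partial Mantel %s x %s: r = %.3f, p = %.4g",
          report$mantel$morphology[[r]], report$mantel$distribution[[r]],
          report$mantel$r[[r]], report$mantel$p[[r]])
    }
  } else miss("mantel")
  cat(lines, sep = "\n")
  invisible(lines)
}
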