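#' Run the full biome-specialization pipeline
#'
#' Orchestrates occupancy scoring, BSI, the richness-constrained null
#' model, DR tip rates and the comparative stage (PGLS of DR on BSI and on
#' log10 range area, phylogenetic ANOVA of specialist DR across biomes,
#' variance partitioning) from a single configuration, writing a
#' machine-readable report plus per-stage CSV/JSON files.
#'
#' The configuration is a list (or path to a JSON file) with elements:
#' \describe{
#'   \item{overlap_csv / occupancy_csv}{input table — either raw overlap
#'     fractions or an already-binary occupancy matrix}
#'   \item{patches_csv, metadata_csv}{optional companions of overlap_csv}
#'   \item{tree_newick}{optional phylogeny; without it the comparative
#'     stages are marked "skipped"}
#'   \item{range_threshold, patch_threshold}{occupancy rules (0.15, 0.50)}
#'   \item{n_reps}{null-model randomizations (default 10000)}
#'   \item{seed}{master seed (default 1)}
#'   \item{lambda}{PGLS lambda mode, "ML" or a number (default "ML")}
#'   \item{area_transform}{"log10" (default) or "identity"}
#'   \item{anova_n_sim}{phylogenetic-ANOVA simulations (default 1000)}
#'   \item{out_dir}{output directory}
#' }
#'
#' Subfamily-stratified BSI summaries run automatically when the metadata
#' carries a `subfamily` column.
#'
#' @param config list or path to a JSON config file.
#' @return The report (list), invisibly also written to
#'   `out_dir/report.json`. Stage outputs: occupancy.csv, bsi.csv,
#'   specialists.csv, null_model.json, rates.csv, pgls.json, anova.json,
#'   varpart.json.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  cfg <- utils::modifyList(list(range_threshold = 0.15,
                                patch_threshold = 0.50,
                                n_reps = 10000, seed = 1L, lambda = "ML",
                                area_transform = "log10",
                                anova_n_sim = 1000,
                                out_dir = "biomediv_run"), config)
  for (f in c("overlap_csv", "occupancy_csv", "patches_csv",
              "metadata_csv", "tree_newick"))
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
      stop("config file does not exist: ", cfg[[f]], " (", f, ")")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }
  report <- list(config = cfg[setdiff(names(cfg), "out_dir")])
  stage <- "occupancy"
  tryCatch({
    # ---- occupancy ----
    meta <- NULL
    if (!is.null(cfg$overlap_csv)) {
      ov <- read_overlap_csv(cfg$overlap_csv, cfg$patches_csv,
                             cfg$metadata_csv)
      meta <- ov$metadata
      occ <- apply_occupancy_rules(ov, cfg$range_threshold,
                                   cfg$patch_threshold)
      if (length(attr(occ, "unplaced")) > 0)
        say("occupancy: %d species failed both rules and were excluded: %s",
            length(attr(occ, "unplaced")),
            paste(attr(occ, "unplaced"), collapse = ", "))
    } else if (!is.null(cfg$occupancy_csv)) {
      occ <- read_occupancy_csv(cfg$occupancy_csv)
      if (!is.null(cfg$metadata_csv))
        meta <- utils::read.csv(cfg$metadata_csv, comment.char = "#")
    } else stop("config needs overlap_csv or occupancy_csv")
    say("occupancy: %d species x %d biomes", nrow(occ), ncol(occ))
    write_occupancy_csv(occ, file.path(cfg$out_dir, "occupancy.csv"))

    # ---- BSI ----
    stage <- "bsi"
    prof <- compute_bsi(occ)
    s <- attr(prof, "summary")
    utils::write.csv(as.data.frame(prof),
                     file.path(cfg$out_dir, "bsi.csv"), row.names = FALSE)
    spec_tab <- specialist_table(occ, prof)
    utils::write.csv(spec_tab, file.path(cfg$out_dir, "specialists.csv"),
                     row.names = FALSE)
    report$bsi <- list(n_species = s$n_species, mean_bsi = s$mean_bsi,
                       class_counts = as.list(s$class_counts),
                       category_counts = as.list(s$category_counts),
                       category_shares = as.list(stats::setNames(
                         s$category_shares,
                         names(s$category_counts))))
    say("bsi: mean %.3f, %d specialists (%.1f%%)", s$mean_bsi,
        s$category_counts[["specialist"]], 100 * s$category_shares[1])

    if (!is.null(meta) && "subfamily" %in% names(meta)) {
      report$bsi_by_subfamily <- lapply(
        split(as.character(meta$species), meta$subfamily), function(sp) {
          keep <- rownames(occ) %in% sp
          if (sum(keep) < 2) return(NULL)
          sub <- compute_bsi(occupancy_matrix(unclass(occ)[keep, ,
                                                           drop = FALSE]))
          ss <- attr(sub, "summary")
          list(n_species = ss$n_species, mean_bsi = ss$mean_bsi,
               specialist_share = ss$category_shares[1])
        })
      say("bsi: subfamily-stratified summaries for %d subfamilies",
          length(report$bsi_by_subfamily))
    }

    # ---- null model ----
    stage <- "null_model"
    nm <- run_null_model(occ, n_reps = cfg$n_reps, seed = cfg$seed)
    report$null_model <- list(
      n_reps = nm$n_reps, seed = nm$seed,
      observed_bsi_counts = as.list(nm$observed$bsi_counts),
      expected_bsi_counts = as.list(nm$expected$bsi_counts),
      bsi_pvalues = as.list(nm$pvalues$bsi_counts),
      bsi_stars = as.list(nm$stars$bsi_counts),
      specialists = list(
        biome = colnames(unclass(occ)),
        observed = unname(nm$observed$spec_counts),
        observed_prop = unname(nm$observed$spec_props),
        expected = unname(nm$expected$spec_counts),
        expected_prop = unname(nm$expected$spec_props),
        p = unname(nm$pvalues$spec_counts),
        stars = unname(nm$stars$spec_counts)))
    jsonlite::write_json(report$null_model,
                         file.path(cfg$out_dir, "null_model.json"),
                         auto_unbox = TRUE, digits = NA)
    say("null_model: %d reps done", nm$n_reps)

    # ---- comparative stages need a tree ----
    if (is.null(cfg$tree_newick)) {
      report$tip_rates <- "skipped"
      report$pgls <- "skipped"
      report$phylo_anova <- "skipped"
      report$variance_partition <- "skipped"
      say("no tree supplied; comparative stages skipped")
    } else {
      stage <- "tip_rates"
      tree <- read_newick(cfg$tree_newick)
      rates <- dr_statistic(tree)
      write_tip_rates_csv(rates, file.path(cfg$out_dir, "rates.csv"))
      mmatch <- match_species(prof$species, tree$tip.label)
      if (length(mmatch$unmatched_species) > 0)
        say("join: %d species not on the tree: %s",
            length(mmatch$unmatched_species),
            paste(utils::head(mmatch$unmatched_species, 10),
                  collapse = ", "))
      report$join_manifest <- list(
        species_not_on_tree = mmatch$unmatched_species,
        tips_not_in_table = mmatch$unmatched_tips)
      report$tip_rates <- list(n_tips = nrow(rates),
                               mean_dr = mean(rates$dr),
                               mean_dr_by_bsi = as.list(tapply(
                                 rates$dr[match(prof$species,
                                                rates$species)],
                                 prof$bsi, mean, na.rm = TRUE)))

      stage <- "pgls"
      d <- data.frame(species = prof$species, bsi = prof$bsi)
      d$dr <- rates$dr[match_species(d$species, rates$species)$idx]
      d <- d[!is.na(d$dr), , drop = FALSE]
      fit_bsi <- pgls(dr ~ bsi, d, tree, lambda = cfg$lambda)
      report$pgls <- list(dr_bsi = .pgls_report(fit_bsi))
      if (!is.null(meta) && "area_km2" %in% names(meta)) {
        d$area <- meta$area_km2[match(d$species, meta$species)]
        d$area <- if (identical(cfg$area_transform, "log10"))
          log10(d$area) else d$area
        fit_area <- pgls(dr ~ area, d[!is.na(d$area), ], tree,
                         lambda = cfg$lambda)
        report$pgls$dr_area <- .pgls_report(fit_area)
        stage <- "variance_partition"
        dd <- d[!is.na(d$area), ]
        vp <- variance_partition(dd$dr, dd$bsi, dd$area)
        report$variance_partition <- list(
          unique_bsi = vp$unique_x1, unique_area = vp$unique_x2,
          shared = vp$shared, unexplained = vp$unexplained,
          total_explained = vp$r2_both)
        jsonlite::write_json(report$variance_partition,
                             file.path(cfg$out_dir, "varpart.json"),
                             auto_unbox = TRUE, digits = NA)
      } else {
        report$variance_partition <- "skipped"
      }
      jsonlite::write_json(report$pgls,
                           file.path(cfg$out_dir, "pgls.json"),
                           auto_unbox = TRUE, digits = NA)
      say("pgls: DR~BSI slope %.4f (lambda %.3f)",
          fit_bsi$coefficients["bsi", "estimate"], fit_bsi$lambda)

      stage <- "phylo_anova"
      spx <- prof$species[prof$bsi == 1]
      grp <- colnames(unclass(occ))[max.col(unclass(occ)[prof$bsi == 1, ,
                                                         drop = FALSE])]
      names(grp) <- spx
      keep <- !is.na(match_species(spx, tree$tip.label)$idx)
      spx <- spx[keep]; grp <- grp[keep]
      ok_groups <- names(table(grp))[table(grp) >= 2]
      sel <- grp %in% ok_groups
      if (length(unique(grp[sel])) >= 2 && sum(sel) >= 4) {
        yv <- rates$dr[match_species(spx[sel], rates$species)$idx]
        names(yv) <- spx[sel]
        an <- phylo_anova(yv, grp[sel], tree, n_sim = cfg$anova_n_sim,
                          seed = cfg$seed)
        report$phylo_anova <- list(
          f_observed = an$f_observed, p = an$p_phylogenetic,
          n_sim = an$n_sim, group_means = as.list(an$group_means))
        jsonlite::write_json(report$phylo_anova,
                             file.path(cfg$out_dir, "anova.json"),
                             auto_unbox = TRUE, digits = NA)
        say("phylo_anova: F = %.3f, p = %.4g", an$f_observed,
            an$p_phylogenetic)
      } else {
        report$phylo_anova <- "skipped"
        say("phylo_anova skipped: too few specialist groups on the tree")
      }
    }
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })

  report$log <- log_lines
  report$files <- .checksum_outputs(cfg$out_dir)
  jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(report)
}

.pgls_report <- function(fit) {
  list(coefficients = as.list(stats::setNames(fit$coefficients$estimate,
                                              rownames(fit$coefficients))),
       se = as.list(stats::setNames(fit$coefficients$se,
                                    rownames(fit$coefficients))),
       p = as.list(stats::setNames(fit$coefficients$p,
                                   rownames(fit$coefficients))),
       lambda = fit$lambda, loglik = fit$loglik,
       r_squared_adj = fit$r_squared, n = fit$n,
       n_dropped = length(fit$dropped))
}

.checksum_outputs <- function(dir) {
  fs <- list.files(dir, full.names = TRUE)
  fs <- fs[basename(fs) != "report.json"]
  as.list(tools::md5sum(fs))
}
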