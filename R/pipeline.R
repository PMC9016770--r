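## Orchestration of the full study-shaped analysis: spectral clade
## detection, per-clade fits across all trait-free model families with a
## cross-framework comparison by Akaike weight, and a separate
## habitat-dependent section (Mk + stochastic maps + SSE), mirroring the
## layout of empirical diversification summary tables. SSE results are never merged
## into the cross-framework AIC table: its likelihood is computed on tree
## plus tip states, so it is not comparable with the branching-time-only
## families.

#' Analysis configuration
#'
#' @param tree A validated `phylo`, or path to a Newick file.
#' @param traits Tibble (`taxon`, `habitat`), named vector, or path to a
#'   TSV; optional unless the habitat section is requested.
#' @param env Named list of [env_curve()]s (or paths to CSVs).
#' @param f Sampling fraction (default 0.92).
#' @param clades `"auto"` (spectral detection), or a named list of tip
#'   vectors.
#' @param families Character subset of
#'   `c("time", "env", "episodic", "dd", "mk", "sse")`.
#' @param known_species Named vector of known species counts per clade (for
#'   the DD family); defaults to `ceiling(n_tips / f)`.
#' @param dd_variants Diversity-dependent variants to fit (default all
#'   five).
#' @param sse_models Model names passed to [fit_sse_model_space()] (`NULL`
#'   = all 36).
#' @param sse_d Concealed-state count for the SSE section.
#' @param max_shifts,grid_step Episodic search settings.
#' @param n_maps Stochastic maps drawn when the Mk section runs.
#' @param n_starts Starts per optimization.
#' @param seed Master seed.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(tree, traits = NULL, env = list(), f = 0.92,
                            clades = "auto",
                            families = c("time", "env", "episodic", "dd"),
                            known_species = NULL,
                            dd_variants = c("DDL", "DDL+E", "DDX+E", "DD+EL", "DD+EX"),
                            sse_models = NULL, sse_d = 3,
                            max_shifts = 2, grid_step = 0.1, n_maps = 100,
                            n_starts = 3, seed = 1) {
  if (is.character(tree)) {
    if (!file.exists(tree)) abort(paste0("Tree file not found: ", tree))
    tree <- parse_newick(paste(readLines(tree), collapse = ""))
  }
  tree <- validate_phylo(tree)
  if (is.character(traits) && length(traits) == 1 && file.exists(traits)) {
    traits <- read_habitat_tsv(traits, tree)
  }
  env <- lapply(env, function(e) {
    if (is.character(e)) read_env_csv(e) else e
  })
  if (any(c("mk", "sse") %in% families) && is.null(traits)) {
    abort("Habitat families requested but no trait data supplied.")
  }
  if ("env" %in% families && !length(env)) {
    abort("Env family requested but no env curves supplied.")
  }
  if (f <= 0 || f > 1) abort("f must be in (0, 1].")
  structure(
    list(
      tree = tree, traits = traits, env = env, f = f, clades = clades,
      families = families, known_species = known_species,
      dd_variants = dd_variants,
      sse_models = sse_models, sse_d = sse_d, max_shifts = max_shifts,
      grid_step = grid_step, n_maps = n_maps, n_starts = n_starts, seed = seed
    ),
    class = "analysis_config"
  )
}

#' Run the full study-shaped analysis
#'
#' Detects clades (spectral eigengap + k-means, unless given explicitly),
#' fits the requested model families to the whole tree and to each clade,
#' builds a cross-framework comparison via Akaike weights (constant/null,
#' time-dependent, environment-dependent, episodic, diversity-dependent
#' rows; the SSE and Mk results are reported in their own section), and
#' returns everything with a stage-status ledger and a manifest. Reruns
#' with identical config and seeds are deterministic.
#'
#' @param config An [analysis_config()].
#' @param out_dir Optional directory; when given, tables are written as CSV
#'   and the manifest as JSON.
#' @return A `paleodiv_report` list: `clades`, `ltt`, per-clade `fits`,
#'   `comparison`, `mk`, `sse`, `status`, `manifest`.
#' @export
run_full_analysis <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "analysis_config"))
  tree <- config$tree
  status <- list()
  note <- function(stage, ok, detail = "") {
    status[[length(status) + 1]] <<- tibble(stage = stage, ok = ok, detail = detail)
  }
  run_stage <- function(stage, expr) {
    res <- tryCatch(expr, error = function(e) {
      note(stage, FALSE, conditionMessage(e))
      NULL
    })
    if (!is.null(res)) note(stage, TRUE)
    res
  }

  # clade detection
  clades <- run_stage("clade_detection", {
    if (identical(config$clades, "auto")) {
      prof <- laplacian_spectrum(tree)
      k <- prof$k_star
      asg <- cluster_assignment(prof, max(k, 1), seed = config$seed)
      split(asg$taxon, paste0("clade_", asg$cluster))
    } else {
      config$clades
    }
  })
  units <- c(list(whole_tree = tree$tip.label), clades)

  ltt <- run_stage("ltt", {
    bind_rows(lapply(names(units), function(nm) {
      sub <- extract_clade(tree, units[[nm]])
      mutate(ltt_points(sub), unit = nm)
    }))
  })

  fits <- list()
  comparison_rows <- list()
  for (nm in names(units)) {
    sub <- tryCatch(extract_clade(tree, units[[nm]]), error = function(e) NULL)
    if (is.null(sub) || length(sub$tip.label) < 5) {
      note(paste0("fits_", nm), FALSE, "clade too small or not extractable")
      next
    }
    bt <- branching_times(sub)
    unit_fits <- list()
    if ("time" %in% config$families) {
      unit_fits$time <- run_stage(paste0("time_", nm), {
        fit_bd_family(bt, "time", f = config$f,
          n_starts = config$n_starts, seed = config$seed
        )
      })
    }
    if ("env" %in% config$families) {
      unit_fits$env <- run_stage(paste0("env_", nm), {
        envfits <- lapply(names(config$env), function(px) {
          ft <- fit_bd_family(bt, "env", env = config$env[[px]], f = config$f,
            n_starts = config$n_starts, seed = config$seed
          )
          ft$proxy <- px
          ft
        })
        bind_rows(envfits)
      })
    }
    if ("episodic" %in% config$families) {
      unit_fits$episodic <- run_stage(paste0("episodic_", nm), {
        fs <- fit_shifts(bt,
          max_shifts = config$max_shifts,
          grid_step = config$grid_step, f = config$f,
          n_starts = config$n_starts, seed = config$seed
        )
        sel <- select_num_shifts(fs)
        attr(fs, "selected_shifts") <- sel$n_shifts
        fs
      })
    }
    if ("dd" %in% config$families) {
      unit_fits$dd <- run_stage(paste0("dd_", nm), {
        ks <- config$known_species[[nm]] %||% ceiling(length(sub$tip.label) / config$f)
        fit_dd_family(bt,
          f = config$f, known_species = ks, variants = config$dd_variants,
          n_starts = config$n_starts, seed = config$seed
        )
      })
    }
    fits[[nm]] <- unit_fits
    comparison_rows[[nm]] <- cross_framework_table(unit_fits, nm)
  }
  comparison <- bind_rows(comparison_rows)

  mk_res <- NULL
  if ("mk" %in% config$families) {
    mk_res <- run_stage("mk", {
      fit <- fit_mk(tree, config$traits,
        n_starts = config$n_starts,
        seed = config$seed
      )
      marg <- ancestral_marginals(tree, config$traits, fit$Q)
      maps <- stochastic_map(tree, config$traits, fit$Q,
        n_maps = config$n_maps, seed = config$seed, keep_paths = FALSE
      )
      list(fit = fit, marginals = marg, simmap = summarize_maps(maps))
    })
  }

  sse_res <- NULL
  if ("sse" %in% config$families) {
    sse_res <- run_stage("sse", {
      tab <- fit_sse_model_space(tree, config$traits,
        d = config$sse_d,
        f = config$f, models = config$sse_models,
        n_starts = config$n_starts, seed = config$seed
      )
      best <- tab$fit[[1]]
      probs <- if (best$converged) node_state_probs(best) else NULL
      list(table = tab[, setdiff(names(tab), "fit")], best = best, node_probs = probs)
    })
  }

  status_tbl <- bind_rows(status)
  manifest <- list(
    package_version = as.character(utils::packageVersion("paleodiv")),
    seed = config$seed, f = config$f,
    n_tips = length(tree$tip.label),
    crown_age = max(branching_times(tree)),
    families = config$families,
    clades = lapply(units, length),
    settings = config[c("max_shifts", "grid_step", "n_maps", "n_starts", "sse_d")]
  )
  report <- structure(
    list(
      clades = clades, ltt = ltt, fits = fits, comparison = comparison,
      mk = mk_res, sse = sse_res, status = status_tbl, manifest = manifest
    ),
    class = "paleodiv_report"
  )
  if (!is.null(out_dir)) write_report(report, out_dir)
  if (any(!status_tbl$ok)) {
    warn(paste0(
      "Stages failed: ",
      paste(status_tbl$stage[!status_tbl$ok], collapse = ", ")
    ))
  }
  report
}

# best row of each family, on a common schema, cross-compared by wAIC
cross_framework_table <- function(unit_fits, unit) {
  rows <- list()
  tf <- unit_fits$time
  if (!is.null(tf)) {
    null_row <- tf[tf$model %in% c("yule", "bcst_dcst"), ]
    null_best <- null_row[which.min(null_row$aic), ]
    rows$null <- tibble(
      model_type = "null", best_model = null_best$model,
      n_params = null_best$n_params, loglik = null_best$loglik
    )
    tvar <- tf[!tf$model %in% c("yule", "bcst_dcst"), ]
    tbest <- tvar[which.min(tvar$aic), ]
    rows$time <- tibble(
      model_type = "time", best_model = tbest$model,
      n_params = tbest$n_params, loglik = tbest$loglik
    )
  }
  ef <- unit_fits$env
  if (!is.null(ef)) {
    eb <- ef[which.min(ef$aic), ]
    rows$env <- tibble(
      model_type = "env", best_model = paste0(eb$model, "(", eb$proxy, ")"),
      n_params = eb$n_params, loglik = eb$loglik
    )
  }
  sf <- unit_fits$episodic
  if (!is.null(sf)) {
    sel <- attr(sf, "selected_shifts") %||% sf$n_shifts[which.min(sf$aic)]
    sb <- sf[sf$n_shifts == sel, ]
    rows$episodic <- tibble(
      model_type = "episodic", best_model = sb$model,
      n_params = sb$n_params, loglik = sb$loglik
    )
  }
  df <- unit_fits$dd
  if (!is.null(df)) {
    db <- df[which.min(df$aic), ]
    rows$dd <- tibble(
      model_type = "dd", best_model = db$model,
      n_params = db$n_params, loglik = db$loglik
    )
  }
  if (!length(rows)) return(NULL)
  out <- bind_rows(rows)
  out$model <- out$best_model
  tab <- akaike_table(out[, c("model", "n_params", "loglik", "model_type")])
  tab$unit <- unit
  tab[, c(
    "unit", "model_type", "model", "n_params", "loglik", "aic", "delta",
    "weight", "weight_pct", "best"
  )]
}

#' Write a report bundle to disk
#'
#' CSV tables plus a JSON manifest; file names mirror the report fields.
#'
#' @param report A `paleodiv_report`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  wcsv <- function(df, name) {
    if (!is.null(df)) write.csv(df, file.path(out_dir, name), row.names = FALSE)
  }
  wcsv(report$comparison, "comparison.csv")
  wcsv(report$ltt, "ltt.csv")
  wcsv(report$status, "status.csv")
  for (nm in names(report$fits)) {
    uf <- report$fits[[nm]]
    if (!is.null(uf$time)) wcsv(tidy(uf$time), paste0("time_", nm, ".csv"))
    if (!is.null(uf$env)) {
      wcsv(as_tibble(uf$env)[, setdiff(names(uf$env), character(0))],
        paste0("env_", nm, ".csv")
      )
    }
    if (!is.null(uf$episodic)) wcsv(tidy(uf$episodic), paste0("episodic_", nm, ".csv"))
    if (!is.null(uf$dd)) wcsv(tidy(uf$dd), paste0("dd_", nm, ".csv"))
  }
  if (!is.null(report$mk)) {
    wcsv(report$mk$marginals, "mk_marginals.csv")
    wcsv(report$mk$fit$lrt, "mk_lrt.csv")
    wcsv(report$mk$simmap$time_in_state, "mk_time_in_state.csv")
    wcsv(report$mk$simmap$transitions, "mk_transitions.csv")
  }
  if (!is.null(report$sse)) {
    wcsv(report$sse$table, "sse_models.csv")
    wcsv(report$sse$node_probs, "sse_node_probs.csv")
  }
  if (!is.null(report$clades)) {
    asg <- bind_rows(lapply(names(report$clades), function(nm) {
      tibble(taxon = report$clades[[nm]], cluster = nm)
    }))
    utils::write.table(asg, file.path(out_dir, "clusters.tsv"),
      sep = "\t",
      row.names = FALSE, quote = FALSE
    )
  }
  jsonlite::write_json(report$manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(out_dir)
}

#' @export
print.paleodiv_report <- function(x, ...) {
  cat("<paleodiv_report>\n")
  cat("  clades:", paste(names(x$clades), lengths(x$clades),
    sep = "=", collapse = ", "
  ), "\n")
  if (!is.null(x$comparison) && nrow(x$comparison)) {
    best <- x$comparison[x$comparison$best, ]
    for (i in seq_len(nrow(best))) {
      cat(
        "  ", best$unit[i], ": best = ", best$model[i],
        " (wAIC ", sprintf("%.1f%%", best$weight_pct[i]), ")\n",
        sep = ""
      )
    }
  }
  ok <- if (nrow(x$status)) sum(x$status$ok) else 0
  cat("  stages ok:", ok, "/", nrow(x$status), "\n")
  invisible(x)
}
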