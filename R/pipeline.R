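# End-to-end orchestration: selection -> mutant building -> folding ddG ->
# binding ddG -> potential maps -> normal modes -> report.

#' Default desk-scale pipeline configuration
#'
#' Wires the synthetic homolog-alignment scenario and a toy two-domain dimer
#' into a complete run: the selection cascade with the published thresholds,
#' a charge-changing toy mutation on both chains, two energy
#' parameterizations, a coarse potential map with two opposing patches, and
#' the anisotropic network model with the published parameters.
#'
#' @param seed Integer seed recorded in the report and used for all sampling.
#' @param skip Character vector of stage names to skip
#'   (subset of `c("select", "ddg", "bind", "pbmap", "anm")`).
#' @return A `pipeline_config` list.
#' @export
toy_pipeline_config <- function(seed = 1, skip = character()) {
  structure(list(
    seed = seed,
    skip = skip,
    selection = list(
      conservation_threshold = 0.95, window = 2,
      freq_threshold = 0.5, exclude = 149, n_perm = 200, alpha = 1e-6
    ),
    structure = list(n_per_domain = 8, cleft = 12),
    mutations = list(list(chain = "C", site = 5, wt = "A", mut = "D"),
                     list(chain = "D", site = 5, wt = "A", mut = "D")),
    energy = list(param_ids = c("setA", "setB"), minimize = FALSE,
                  terms = c("bonded", "vdw", "coulomb", "gb", "nonpolar")),
    grid = list(scale = 0.75, fill = 55, tol = 1e-4),
    patches = list(cleft = list(chains = c("C", "D"), sites = 5:8),
                   far = list(chains = c("C", "D"), sites = 1:2)),
    anm = list(cutoff = 15, gamma = 1.0, modes = 3, mass = 110)
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file; keys mirror [toy_pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort(paste0("no such config file: ", path))
  cfg <- yaml::read_yaml(path)
  base <- toy_pipeline_config(seed = cfg$seed %||% 1)
  for (k in names(cfg)) base[[k]] <- utils::modifyList(
    if (is.list(base[[k]])) base[[k]] else list(), as.list(cfg[[k]])
  ) %||% cfg[[k]]
  if (!is.list(cfg$seed %||% 1)) base$seed <- cfg$seed %||% 1
  if (!is.null(cfg$skip)) base$skip <- unlist(cfg$skip)
  base
}

run_stage <- function(name, skip, fun) {
  if (name %in% skip) return(structure(list(), class = "skipped_stage"))
  tryCatch(fun(), error = function(e) {
    abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
  })
}

is_skipped <- function(x) inherits(x, "skipped_stage")

#' Run the full engineering pipeline on synthetic inputs
#'
#' Stages run in order: candidate selection on a sampled homolog alignment,
#' mutant building on a toy dimer, folding and binding free-energy changes
#' averaged over parameterizations, a mutant-minus-wild-type potential map
#' with patch statistics, and anisotropic-network mode frequencies.  Any
#' stage can be skipped by config; identical config and seed give identical
#' reports.
#'
#' @param config A `pipeline_config` (see [toy_pipeline_config()],
#'   [read_pipeline_config()]).
#' @return A `run_report` list with one element per stage plus provenance.
#' @export
run_pipeline <- function(config = toy_pipeline_config()) {
  set.seed(config$seed)
  skip <- config$skip %||% character()

  selection <- run_stage("select", skip, function() {
    scen <- table1_msa_spec()
    msa <- synth_msa(scen$spec, seed = config$seed)
    sel <- config$selection
    select_mutations(
      msa, scen$pair, scen$acceptor_id, scen$donor_id,
      start = scen$start_site, exclude = sel$exclude,
      conservation_threshold = sel$conservation_threshold,
      window = sel$window, freq_threshold = sel$freq_threshold,
      n_perm = sel$n_perm, alpha = sel$alpha
    )
  })

  st <- config$structure
  wt <- two_domain_dimer(st$n_per_domain, st$cleft)
  mut <- wt
  for (m in config$mutations) {
    mut <- mutate_residue(mut, m$chain, m$site, m$wt, m$mut)
  }
  sites <- purrr::map(config$mutations, ~ tibble(chain = .x$chain, site = .x$site)) |>
    list_rbind()
  params_list <- lapply(config$energy$param_ids, energy_params)

  ddg <- run_stage("ddg", skip, function() {
    rec <- folding_ddg(wt, mut, sites, params_list,
                       monomers = unique(sites$chain),
                       terms = config$energy$terms,
                       minimize = isTRUE(config$energy$minimize))
    agg <- aggregate_ddg(rec)
    list(records = rec, per_monomer = agg$per_monomer, overall = agg$overall)
  })

  bind <- run_stage("bind", skip, function() {
    rec <- binding_ddg(wt, mut, chains = unique(wt$chain), params_list,
                       terms = config$energy$terms)
    list(records = rec, overall = mean(rec$ddd),
         verdict = classify_binding_effect(mean(rec$ddd)))
  })

  pbmap <- run_stage("pbmap", skip, function() {
    gs <- grid_spec(scale = config$grid$scale, fill = config$grid$fill,
                    tol = config$grid$tol %||% 1e-4)
    g_wt <- solve_lpbe(wt, gs)
    g_mut <- solve_lpbe(mut, gs)
    diffm <- grid_subtract(g_mut, g_wt)
    patches <- purrr::map(config$patches, function(p) {
      tidyr::expand_grid(chain = p$chains, site = p$sites)
    })
    list(diff = diffm, stats = patch_stats(diffm, wt, patches))
  })

  anm <- run_stage("anm", skip, function() {
    a <- config$anm
    modes_wt <- enm_modes(wt, cutoff = a$cutoff, gamma = a$gamma, mass = a$mass)
    modes_mut <- enm_modes(mut, cutoff = a$cutoff, gamma = a$gamma, mass = a$mass)
    take <- function(ms, tag) {
      nz <- which(!ms$rigid)[seq_len(a$modes)]
      tibble(structure = tag, label = "toy", mode = seq_len(a$modes),
             ghz = ms$freq_ghz[nz])
    }
    list(wt = modes_wt, mut = modes_mut,
         table = mode_table(bind_rows(take(modes_wt, "WT"), take(modes_mut, "mut")),
                            modes = seq_len(a$modes)))
  })

  structure(list(
    selection = selection, ddg = ddg, binding = bind, pbmap = pbmap, anm = anm,
    provenance = list(
      seed = config$seed,
      config_hash = rlang::hash(config),
      package_version = as.character(utils::packageVersion("mutsmith")),
      units = c(energy = "kcal/mol", potential = "kT/e", frequency = "GHz")
    )
  ), class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("mutsmith pipeline report (seed", x$provenance$seed, ")\n")
  for (nm in c("selection", "ddg", "binding", "pbmap", "anm")) {
    status <- if (is_skipped(x[[nm]])) "skipped" else "done"
    cat(sprintf("  %-10s %s\n", nm, status))
  }
  invisible(x)
}

report_to_list <- function(report) {
  num <- function(v) round(unname(v), 6)
  out <- list(provenance = report$provenance[c("seed", "config_hash", "package_version")])
  out$selection <- if (is_skipped(report$selection)) "skipped" else list(
    stages = purrr::map2(report$selection$stages$stage, report$selection$stages$sites,
                         function(s, sites) list(stage = s, sites = sites)),
    final = purrr::pmap(report$selection$final[c("site", "wt_residue", "target_residue")],
                        function(site, wt_residue, target_residue) {
                          list(site = site, wt = wt_residue, target = target_residue)
                        })
  )
  out$ddg <- if (is_skipped(report$ddg)) "skipped" else list(
    records = purrr::pmap(report$ddg$records, function(param, monomer, ddg) {
      list(param = param, monomer = monomer, ddg = num(ddg))
    }),
    overall_kcal_mol = num(report$ddg$overall)
  )
  out$binding <- if (is_skipped(report$binding)) "skipped" else list(
    overall_kcal_mol = num(report$binding$overall),
    verdict = report$binding$verdict
  )
  out$pbmap <- if (is_skipped(report$pbmap)) "skipped" else list(
    patch_stats = purrr::pmap(report$pbmap$stats,
                              function(patch, n_points, mean, min, max) {
                                list(patch = patch, n_points = n_points,
                                     mean_kt_e = num(mean), min_kt_e = num(min),
                                     max_kt_e = num(max))
                              })
  )
  out$anm <- if (is_skipped(report$anm)) "skipped" else list(
    table = purrr::pmap(
      report$anm$table[c("structure", "mode", "mean_ghz")],
      function(structure, mode, mean_ghz) {
        list(structure = structure, mode = mode, mean_ghz = num(mean_ghz))
      })
  )
  out
}

#' Render a pipeline report to files
#'
#' @param report A `run_report`.
#' @param dir Output directory (created if needed).
#' @param format One or more of `"json"`, `"tsv"`, `"markdown"`.
#' @return Character vector of written paths, invisibly.
#' @export
render_report <- function(report, dir, format = c("json", "tsv", "markdown")) {
  format <- match.arg(format, several.ok = TRUE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  if ("json" %in% format) {
    p <- file.path(dir, "report.json")
    jsonlite::write_json(report_to_list(report), p, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    written <- c(written, p)
  }
  if ("tsv" %in% format) {
    tables <- list()
    if (!is_skipped(report$selection)) tables$selection <- tidy(report$selection)
    if (!is_skipped(report$ddg)) tables$ddg <- report$ddg$records
    if (!is_skipped(report$binding)) tables$binding <- report$binding$records
    if (!is_skipped(report$pbmap)) tables$patches <- report$pbmap$stats
    if (!is_skipped(report$anm)) tables$modes <- report$anm$table
    for (nm in names(tables)) {
      p <- file.path(dir, paste0(nm, ".tsv"))
      df <- tables[[nm]]
      df <- df[, !vapply(df, is.list, logical(1)), drop = FALSE]
      num_cols <- vapply(df, is.numeric, logical(1))
      df[num_cols] <- lapply(df[num_cols], function(v) round(v, 2))
      write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
      written <- c(written, p)
    }
  }
  if ("markdown" %in% format) {
    p <- file.path(dir, "report.md")
    lines <- c("# Engineering pipeline report", "",
               paste0("seed: ", report$provenance$seed))
    for (nm in c("selection", "ddg", "binding", "pbmap", "anm")) {
      lines <- c(lines, "", paste0("## ", nm))
      if (is_skipped(report[[nm]])) {
        lines <- c(lines, "", "_skipped by configuration_")
      } else if (nm == "selection") {
        muts <- report$selection$final
        lines <- c(lines, "", paste0("final mutations: ",
                                     paste0(muts$wt_residue, muts$site,
                                            muts$target_residue, collapse = ", ")))
      } else if (nm == "ddg") {
        lines <- c(lines, "", sprintf("overall folding ddG: %.2f kcal/mol",
                                      report$ddg$overall))
      } else if (nm == "binding") {
        lines <- c(lines, "", sprintf("overall binding dddG: %.2f kcal/mol (%s)",
                                      report$binding$overall, report$binding$verdict))
      } else if (nm == "pbmap") {
        s <- report$pbmap$stats
        lines <- c(lines, "", paste0(s$patch, ": mean ",
                                     sprintf("%.3f", s$mean), " kT/e", collapse = "; "))
      } else if (nm == "anm") {
        t <- report$anm$table
        lines <- c(lines, "", paste(sprintf("%s mode %d: %.2f GHz", t$structure,
                                            t$mode, t$mean_ghz), collapse = "; "))
      }
    }
    writeLines(lines, p)
    written <- c(written, p)
  }
  invisible(written)
}
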