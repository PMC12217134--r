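# End-to-end orchestration: per-specimen tissue set -> morphometry table ->
# cohort statistics report. The YAML run config mirrors the measurement
# defaults: species presets fix the increment (rat 0.1 mm, mouse 0.05 mm),
# midsubstance fraction 0.50, 10 stations, 3 slices per region, alpha 0.05.

#' Read and validate a run configuration
#'
#' @param path YAML file. Recognized keys: `specimen`, `species`,
#'   `increment`, `csa_method`, `midsubstance_fraction`, `mode`,
#'   `n_stations`, `slice_thickness`, `footprint` (mm^2 number or label
#'   volume file), `ligaments` (list of `name`/`path`), `menisci` (list of
#'   `name`/`path`/`side`/`frame`), `seed`, `out`.
#' @return The validated config list (class `run_config`).
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg, dir = dirname(path))
}

validate_run_config <- function(cfg, dir = ".") {
  if (is.null(cfg$specimen)) cfg$specimen <- "specimen1"
  cfg$species <- match.arg(cfg$species, c("rat", "mouse"))
  if (is.null(cfg$increment)) {
    cfg$increment <- if (cfg$species == "rat") 0.1 else 0.05
  }
  if (is.null(cfg$csa_method)) cfg$csa_method <- "hull"
  if (is.null(cfg$midsubstance_fraction)) cfg$midsubstance_fraction <- 0.5
  if (is.null(cfg$mode)) cfg$mode <- "max"
  if (is.null(cfg$n_stations)) cfg$n_stations <- 10L
  if (is.null(cfg$slice_thickness)) cfg$slice_thickness <- cfg$increment
  if (is.null(cfg$seed)) cfg$seed <- 1L
  resolve <- function(p) {
    if (file.exists(p)) p else file.path(dir, p)
  }
  for (i in seq_along(cfg$ligaments)) {
    cfg$ligaments[[i]]$path <- resolve(cfg$ligaments[[i]]$path)
    if (!file.exists(cfg$ligaments[[i]]$path)) {
      stop("ligament file not found: ", cfg$ligaments[[i]]$path)
    }
  }
  for (i in seq_along(cfg$menisci)) {
    cfg$menisci[[i]]$path <- resolve(cfg$menisci[[i]]$path)
    if (!file.exists(cfg$menisci[[i]]$path)) {
      stop("meniscus file not found: ", cfg$menisci[[i]]$path)
    }
    if (!is.null(cfg$menisci[[i]]$frame)) {
      cfg$menisci[[i]]$frame <- resolve(cfg$menisci[[i]]$frame)
      if (!file.exists(cfg$menisci[[i]]$frame)) {
        stop("frame file not found: ", cfg$menisci[[i]]$frame)
      }
    }
  }
  if (is.character(cfg$footprint)) {
    cfg$footprint <- resolve(cfg$footprint)
    if (!file.exists(cfg$footprint)) {
      stop("footprint file not found: ", cfg$footprint)
    }
  }
  class(cfg) <- "run_config"
  cfg
}

read_frame_file <- function(path, side) {
  rot <- if (is.null(path)) diag(3) else {
    m <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (is.list(m) && !is.null(m$rotation)) m <- m$rotation
    matrix(unlist(m), 3, 3, byrow = TRUE)
  }
  anatomic_frame(rot, side)
}

#' Run the full morphometry pipeline for one specimen
#'
#' Ligaments: surface point cloud, principal-axis alignment, fixed-increment
#' slicing, midsubstance CSA, and (when a footprint is available) normalized
#' CSA. Menisci: anatomic orientation, three regional width/height measures.
#' Per-tissue failures are recorded as warnings and skipped; the run fails
#' only if every tissue fails.
#'
#' @param cfg a `run_config` (see [read_run_config()]) or a list with the
#'   same fields.
#' @return A data frame of class `morphometry_table` with columns
#'   `specimen`, `species`, `tissue`, `side`, `region`, `measure`, `value`,
#'   `units`; provenance (config, seed, package version) in
#'   `attr(, "provenance")`.
#' @export
run_specimen <- function(cfg) {
  if (!inherits(cfg, "run_config")) cfg <- validate_run_config(cfg)
  mcfg <- morphometry_config(cfg$species, cfg$increment,
                             cfg$midsubstance_fraction, cfg$csa_method)
  rows <- list()
  failures <- 0L
  attempts <- 0L
  add <- function(tissue, side, region, measure, value, units) {
    rows[[length(rows) + 1L]] <<- data.frame(
      specimen = cfg$specimen, species = cfg$species, tissue = tissue,
      side = side, region = region, measure = measure, value = value,
      units = units, stringsAsFactors = FALSE)
  }
  footprint_area <- NULL
  if (!is.null(cfg$footprint)) {
    footprint_area <- if (is.numeric(cfg$footprint)) cfg$footprint else
      plateau_footprint(read_label_volume(cfg$footprint))$area
    add("tibia", NA, NA, "footprint_area", footprint_area, "mm^2")
  }
  for (lg in cfg$ligaments) {
    attempts <- attempts + 1L
    ok <- tryCatch({
      mesh <- read_stl(lg$path, name = lg$name)
      al <- align_longitudinal(mesh_to_pointcloud(mesh))
      amesh <- if (mcfg$csa_method == "plane_intersection") {
        apply_alignment(mesh, al$frame)
      } else NULL
      prof <- slice_profile(al$cloud, mcfg, mesh = amesh)
      add(lg$name, NA, NA, "midsubstance_csa", prof$midsubstance_csa, "mm^2")
      if (!is.null(footprint_area)) {
        add(lg$name, NA, NA, "normalized_csa",
            normalize_csa(prof$midsubstance_csa, footprint_area), "%")
      }
      TRUE
    }, error = function(e) {
      warning("ligament '", lg$name, "' failed: ", conditionMessage(e))
      FALSE
    })
    if (!ok) failures <- failures + 1L
  }
  for (mn in cfg$menisci) {
    attempts <- attempts + 1L
    ok <- tryCatch({
      mesh <- read_stl(mn$path, name = mn$name)
      frame <- read_frame_file(mn$frame, mn$side)
      reg <- meniscus_regions(mesh, frame, cfg$slice_thickness,
                              cfg$n_stations, cfg$mode)
      for (i in seq_len(nrow(reg))) {
        add(mn$name, mn$side, reg$region[i], "width", reg$width_mm[i], "mm")
        add(mn$name, mn$side, reg$region[i], "height", reg$height_mm[i], "mm")
      }
      TRUE
    }, error = function(e) {
      warning("meniscus '", mn$name, "' failed: ", conditionMessage(e))
      FALSE
    })
    if (!ok) failures <- failures + 1L
  }
  if (attempts > 0L && failures == attempts) {
    stop("all tissues failed; nothing to report")
  }
  out <- do.call(rbind, rows)
  attr(out, "provenance") <- list(
    config = unclass(cfg), seed = cfg$seed,
    version = as.character(utils::packageVersion("rodentmorph")))
  class(out) <- c("morphometry_table", class(out))
  out
}

#' Cohort-level statistics over morphometry tables
#'
#' Ligament CSA: per-species Kruskal-Wallis over ligament type plus post hoc
#' comparisons (Tukey's HSD on ranks, Bonferroni-adjusted). Normalized CSA:
#' two-way species x ligament aligned-rank-transform factorial plus pairwise
#' rank-sum species contrasts per ligament. Menisci: per-species side x
#' region ART for widths and heights plus pairwise region rank-sum post
#' hocs. Group means and SDs are reported rounded to two decimals (half away
#' from zero); full precision is kept in the returned tables.
#'
#' @param tables a `morphometry_table` or list of them.
#' @param alpha significance level (default 0.05).
#' @return A list of class `cohort_report` with data frames `summary`,
#'   `omnibus`, `posthoc`.
#' @export
run_cohort <- function(tables, alpha = 0.05) {
  tab <- if (is.data.frame(tables)) tables else do.call(rbind, tables)
  if (length(unique(tab$specimen)) < 2L) stop("need >= 2 specimens")
  omnibus <- list()
  posthoc <- list()
  orow <- function(scope, sr) {
    df <- sr$df
    data.frame(scope = scope, test = sr$test_name,
               statistic = sr$statistic, df1 = df[1],
               df2 = if (length(df) > 1) df[2] else NA_real_,
               p = sr$p_value, p_adjusted = sr$p_adjusted,
               p_display = p_display(sr$p_adjusted),
               stringsAsFactors = FALSE)
  }
  prow <- function(scope, sr) {
    data.frame(scope = scope, test = sr$test_name,
               comparison = sr$comparison, statistic = sr$statistic,
               p = sr$p_value, p_adjusted = sr$p_adjusted,
               p_display = p_display(sr$p_adjusted),
               stringsAsFactors = FALSE)
  }
  # ligament CSA per species
  csa <- tab[tab$measure == "midsubstance_csa", ]
  for (sp in unique(csa$species)) {
    d <- csa[csa$species == sp, ]
    if (length(unique(d$tissue)) < 2L) next
    groups <- split(d$value, d$tissue)
    kw <- kruskal_wallis(groups, alpha = alpha)
    omnibus[[length(omnibus) + 1L]] <- orow(paste0("csa/", sp), kw)
    if (kw$p_value < alpha) {
      for (sr in posthoc_pairwise(groups, "tukey_on_ranks", alpha)) {
        posthoc[[length(posthoc) + 1L]] <- prow(paste0("csa/", sp), sr)
      }
    }
  }
  # normalized CSA: species x ligament ART
  ncsa <- tab[tab$measure == "normalized_csa", ]
  if (nrow(ncsa) > 0L && length(unique(ncsa$species)) >= 2L) {
    art <- art_anova_2way(ncsa$value, ncsa$species, ncsa$tissue, alpha)
    for (ef in names(art)) {
      omnibus[[length(omnibus) + 1L]] <-
        orow(paste0("normalized_csa/", c(A = "species", B = "ligament",
                                         AB = "species:ligament")[ef]),
             art[[ef]])
    }
    praw <- list()
    for (tg in unique(ncsa$tissue)) {
      d <- ncsa[ncsa$tissue == tg, ]
      sps <- unique(d$species)
      rs <- rank_sum(d$value[d$species == sps[1]],
                     d$value[d$species == sps[2]])
      rs$comparison <- paste0(tg, ": ", sps[1], "-", sps[2])
      praw[[tg]] <- rs
    }
    adj <- adjust_bonferroni(vapply(praw, function(s) s$p_value, numeric(1)))
    for (i in seq_along(praw)) {
      praw[[i]]$p_adjusted <- adj[i]
      posthoc[[length(posthoc) + 1L]] <- prow("normalized_csa", praw[[i]])
    }
  }
  # menisci: side x region ART per species and measure
  men <- tab[tab$measure %in% c("width", "height"), ]
  for (sp in unique(men$species)) {
    for (ms in c("width", "height")) {
      d <- men[men$species == sp & men$measure == ms, ]
      if (nrow(d) == 0L || length(unique(d$side)) < 2L) next
      art <- art_anova_2way(d$value, d$side, d$region, alpha)
      for (ef in names(art)) {
        omnibus[[length(omnibus) + 1L]] <-
          orow(paste0("meniscus_", ms, "/", sp, "/",
                      c(A = "side", B = "region", AB = "side:region")[ef]),
               art[[ef]])
      }
      groups <- split(d$value, d$region)
      for (sr in posthoc_pairwise(groups, "rank_sum", alpha)) {
        posthoc[[length(posthoc) + 1L]] <-
          prow(paste0("meniscus_", ms, "/", sp), sr)
      }
    }
  }
  key <- paste(tab$species, tab$tissue, tab$side, tab$region, tab$measure)
  summ <- do.call(rbind, lapply(split(tab, key), function(d) {
    data.frame(species = d$species[1], tissue = d$tissue[1],
               side = d$side[1], region = d$region[1],
               measure = d$measure[1], n = nrow(d),
               mean = round_half_away(mean(d$value), 2L),
               sd = round_half_away(stats::sd(d$value), 2L),
               units = d$units[1], stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  structure(list(summary = summ,
                 omnibus = if (length(omnibus)) do.call(rbind, omnibus)
                           else NULL,
                 posthoc = if (length(posthoc)) do.call(rbind, posthoc)
                           else NULL,
                 alpha = alpha),
            class = "cohort_report")
}

# report convention: p values below 1e-3 print as "<0.001"
p_display <- function(p) {
  ifelse(is.na(p), NA_character_,
         ifelse(p < 1e-3, "<0.001", sprintf("%.3f", p)))
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("cohort report (alpha =", x$alpha, ")\n\nGroup summaries:\n")
  print(utils::head(x$summary, 20))
  if (!is.null(x$omnibus)) {
    cat("\nOmnibus tests:\n")
    print(x$omnibus[, c("scope", "test", "statistic", "df1", "df2",
                        "p_display")])
  }
  if (!is.null(x$posthoc)) {
    cat("\nPost hoc comparisons (Bonferroni-adjusted):\n")
    print(x$posthoc[, c("scope", "comparison", "p_display")])
  }
  invisible(x)
}
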