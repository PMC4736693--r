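#' A single meal-window profile
#'
#' The unit of analysis: one time series of plasma insulin concentrations for
#' a given woman, visit and meal, together with its dosing schedule and
#' per-profile observed data (body weight, 5-h post-meal reference time).
#'
#' @param woman,visit,meal identifiers; `meal` is `"dinner"` or
#'   `"breakfast"`.
#' @param times observation times, minutes since midnight day 1 (strictly
#'   increasing).
#' @param conc plasma insulin concentrations, pmol/l.
#' @param dosing a [dosing_schedule()].
#' @param wt body weight, kg.
#' @param t_end 5-h post-meal reference time, minutes.
#' @param t_start start of the profile window, minutes.
#' @param unit_conversion pmol per mU (see [profile_context()]).
#' @export
pk_profile <- function(woman, visit, meal, times, conc, dosing, wt, t_end,
                       t_start = 0, unit_conversion = 6) {
  stopifnot(length(times) == length(conc), length(times) >= 1)
  if (any(diff(times) <= 0)) stop("observation times must be strictly increasing")
  stopifnot(meal %in% c("dinner", "breakfast"))
  structure(list(
    profile_id = sprintf("w%02d_v%d_%s", as.integer(woman), as.integer(visit),
                         meal),
    woman = as.integer(woman), visit = as.integer(visit), meal = meal,
    times = as.numeric(times), conc = as.numeric(conc), dosing = dosing,
    wt = wt, t_end = t_end, t_start = t_start,
    unit_conversion = unit_conversion
  ), class = "pk_profile")
}

profile_ctx <- function(p) {
  profile_context(p$wt, p$t_end, p$t_start, p$unit_conversion)
}

#' A trial dataset
#'
#' @param profiles list of [pk_profile()] objects (unique profile ids).
#' @param design optional [build_design()] output matching the profiles.
#' @param excluded named character vector: profile id -> reason for
#'   exclusion from analysis.
#' @export
pk_dataset <- function(profiles, design = NULL, excluded = character()) {
  ids <- vapply(profiles, function(p) p$profile_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate profile ids: ",
                               ids[duplicated(ids)][1])
  names(profiles) <- ids
  if (!is.null(design) && !setequal(design$profile_id, ids))
    stop("covariate design rows do not match profiles one-to-one")
  structure(list(profiles = profiles, design = design, excluded = excluded),
            class = "pk_dataset")
}

#' @export
print.pk_dataset <- function(x, ...) {
  n <- length(x$profiles)
  nw <- length(unique(vapply(x$profiles, `[[`, integer(1), "woman")))
  cat("<pk_dataset>", n, "profiles from", nw, "women;",
      length(x$excluded), "excluded\n")
  if (!is.null(x$design))
    cat("  covariate design:", ncol(x$design$X), "columns (",
        sum(x$design$group == "continuous"), "continuous,",
        sum(x$design$group == "binary"), "binary,",
        sum(x$design$group == "interaction"), "interaction )\n")
  invisible(x)
}

#' Profiles retained for analysis
#' @param dataset a [pk_dataset()].
#' @export
included_profiles <- function(dataset) {
  dataset$profiles[setdiff(names(dataset$profiles), names(dataset$excluded))]
}

# woman / woman-visit / woman-meal index structure used by the multi-level
# population models; indices follow first appearance in the profile list so
# the construction never depends on string collation
hier_index <- function(profiles) {
  woman <- vapply(profiles, `[[`, integer(1), "woman")
  visit <- vapply(profiles, `[[`, integer(1), "visit")
  meal <- vapply(profiles, `[[`, character(1), "meal")
  wkey <- as.character(woman)
  vkey <- paste(woman, visit, sep = ":")
  mkey <- paste(woman, meal, sep = ":")
  wlev <- unique(wkey); vlev <- unique(vkey); mlev <- unique(mkey)
  wi <- match(wkey, wlev); vi <- match(vkey, vlev); mi <- match(mkey, mlev)
  list(
    profile_id = names(profiles),
    woman = wi, n_women = length(wlev),
    visit = vi, n_visits = length(vlev),
    meal = mi, n_meals = length(mlev),
    woman_levels = wlev, visit_levels = vlev, meal_levels = mlev,
    woman_of_visit = wi[match(vlev, vkey)],
    woman_of_meal = wi[match(mlev, mkey)]
  )
}

#' Build the standardized covariate design matrix
#'
#' Arranges the per-profile factor values into an n x c matrix. Continuous
#' factors are centred and scaled to unit sd (over the supplied profiles);
#' binary factors become 0/1 indicators; the study and mealtime factors are
#' replaced by four mutually exclusive study-by-mealtime interaction
#' indicators (study 1 breakfast, study 1 dinner, study 2 breakfast, study 2
#' dinner), exactly one of which is 1 per profile. With the trial's 13
#' factors this yields 15 candidate columns (7 continuous, 4 binary, 4
#' interaction).
#'
#' @param factors data frame with a `profile_id` column plus one column per
#'   factor. No missing values are allowed (no imputation is performed).
#' @param types named character vector mapping factor columns to
#'   `"continuous"` or `"binary"`.
#' @param study_col,meal_col names of the study (1/2) and mealtime
#'   (`"breakfast"`/`"dinner"`) columns to expand into interactions; set to
#'   `NULL` to skip interaction expansion.
#' @return list of class `covariate_design` with elements `X` (matrix),
#'   `group` (per-column `"continuous"`/`"binary"`/`"interaction"`),
#'   `center`, `scale` (per-column standardization record) and `profile_id`.
#' @export
build_design <- function(factors, types, study_col = "study",
                         meal_col = "meal") {
  stopifnot("profile_id" %in% names(factors))
  fac_cols <- names(types)
  missing_cols <- setdiff(c(fac_cols, study_col, meal_col), names(factors))
  if (length(missing_cols))
    stop("factor columns not found: ", paste(missing_cols, collapse = ", "))
  for (cc in c(fac_cols, study_col, meal_col)) {
    bad <- is.na(factors[[cc]])
    if (any(bad))
      stop("missing value for factor '", cc, "' in profile ",
           factors$profile_id[which(bad)[1]])
  }
  cols <- list(); group <- character(); center <- numeric(); scl <- numeric()
  for (cc in fac_cols) {
    v <- factors[[cc]]
    if (types[[cc]] == "continuous") {
      m <- mean(v); s <- sd(v)
      if (!is.finite(s) || s == 0)
        stop("continuous factor '", cc, "' is constant; cannot standardize")
      cols[[cc]] <- (v - m) / s
      group <- c(group, "continuous"); center <- c(center, m)
      scl <- c(scl, s)
    } else if (types[[cc]] == "binary") {
      u <- sort(unique(v))
      if (!all(v %in% c(0, 1)))
        stop("binary factor '", cc, "' must be coded 0/1 (found: ",
             paste(u, collapse = ","), ")")
      cols[[cc]] <- as.numeric(v)
      group <- c(group, "binary"); center <- c(center, 0); scl <- c(scl, 1)
    } else stop("unknown factor type '", types[[cc]], "' for '", cc, "'")
  }
  if (!is.null(study_col) && !is.null(meal_col)) {
    st <- factors[[study_col]]; ml <- factors[[meal_col]]
    stopifnot(all(st %in% c(1, 2)), all(ml %in% c("breakfast", "dinner")))
    cells <- list(study1_breakfast = st == 1 & ml == "breakfast",
                  study1_dinner = st == 1 & ml == "dinner",
                  study2_breakfast = st == 2 & ml == "breakfast",
                  study2_dinner = st == 2 & ml == "dinner")
    for (nm in names(cells)) {
      cols[[nm]] <- as.numeric(cells[[nm]])
      group <- c(group, "interaction"); center <- c(center, 0)
      scl <- c(scl, 1)
    }
  }
  X <- do.call(cbind, cols)
  rownames(X) <- factors$profile_id
  structure(list(X = X, group = group,
                 center = setNames(center, colnames(X)),
                 scale = setNames(scl, colnames(X)),
                 profile_id = factors$profile_id),
            class = "covariate_design")
}

#' Undo the standardization of a design column
#' @param design a `covariate_design`.
#' @param name column name.
#' @param x_std standardized values.
#' @export
destandardize <- function(design, name, x_std) {
  x_std * design$scale[[name]] + design$center[[name]]
}

#' Restrict a covariate design to a subset of profiles
#'
#' Keeps the stored full-data standardization (centering/scaling is not
#' recomputed), so refits on subsets of profiles use the original scale.
#' @param design a `covariate_design`.
#' @param profile_ids ids to keep, in order.
#' @export
subset_design <- function(design, profile_ids) {
  idx <- match(profile_ids, design$profile_id)
  if (anyNA(idx)) stop("unknown profile ids in subset_design")
  out <- design
  out$X <- design$X[idx, , drop = FALSE]
  out$profile_id <- profile_ids
  out
}

# ---------------------------------------------------------------------------
# delimited-file I/O
# ---------------------------------------------------------------------------

#' Read / write a trial dataset as delimited text
#'
#' The on-disk format is five tab-separated files in `dir`:
#' `observations.tsv` (`profile_id`, `time_min`, `concentration_pmol_l`),
#' `dosing.tsv` (`profile_id`, `kind` in basal/bolus, `start_min`,
#' `end_min_or_duration`, `amount` — U/h for basal, U for bolus),
#' `profiles.tsv` (ids, woman/visit/meal, weight, window times) and
#' `covariates.tsv` plus `covariate_types.tsv` (factor schema) when a
#' covariate table is present. Reading is lossless with deterministic
#' ordering by (woman, visit, meal, time).
#'
#' @param dir directory path.
#' @param dataset a [pk_dataset()].
#' @return `read_dataset()` returns a [pk_dataset()]; `write_dataset()`
#'   returns `dir` invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pr <- dataset$profiles
  obs <- do.call(rbind, lapply(pr, function(p)
    data.frame(profile_id = p$profile_id, time_min = p$times,
               concentration_pmol_l = p$conc)))
  dos <- do.call(rbind, lapply(pr, function(p) {
    rbind(
      if (nrow(p$dosing$basal))
        data.frame(profile_id = p$profile_id, kind = "basal",
                   start_min = p$dosing$basal$start,
                   end_min_or_duration = p$dosing$basal$end,
                   amount = p$dosing$basal$rate_mU_min * 60 / 1000),
      if (nrow(p$dosing$bolus))
        data.frame(profile_id = p$profile_id, kind = "bolus",
                   start_min = p$dosing$bolus$start,
                   end_min_or_duration = p$dosing$bolus$duration,
                   amount = p$dosing$bolus$dose_mU / 1000))
  }))
  meta <- do.call(rbind, lapply(pr, function(p)
    data.frame(profile_id = p$profile_id, woman = p$woman, visit = p$visit,
               meal = p$meal, weight_kg = p$wt, t_end_min = p$t_end,
               t_start_min = p$t_start,
               unit_conversion = p$unit_conversion)))
  wr <- function(d, f) write.table(d, file.path(dir, f), sep = "\t",
                                   row.names = FALSE, quote = FALSE)
  wr(obs, "observations.tsv"); wr(dos, "dosing.tsv"); wr(meta, "profiles.tsv")
  if (!is.null(dataset$design)) {
    d <- dataset$design
    raw <- as.data.frame(d$X)
    # store destandardized continuous values so the file carries natural units
    for (j in seq_along(d$group)) if (d$group[j] == "continuous")
      raw[[j]] <- raw[[j]] * d$scale[j] + d$center[j]
    raw <- cbind(profile_id = d$profile_id, raw)
    wr(raw, "covariates.tsv")
    wr(data.frame(factor = colnames(d$X), type = d$group),
       "covariate_types.tsv")
  }
  if (length(dataset$excluded))
    wr(data.frame(profile_id = names(dataset$excluded),
                  reason = unname(dataset$excluded)), "excluded.tsv")
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  rd <- function(f) read.delim(file.path(dir, f), stringsAsFactors = FALSE)
  obs <- rd("observations.tsv"); dos <- rd("dosing.tsv")
  meta <- rd("profiles.tsv")
  dup <- duplicated(obs[c("profile_id", "time_min")])
  if (any(dup))
    stop("duplicated observation time: profile ", obs$profile_id[dup][1],
         " at t = ", obs$time_min[dup][1])
  if (!all(dos$profile_id %in% meta$profile_id))
    stop("dosing references unknown profile: ",
         setdiff(dos$profile_id, meta$profile_id)[1])
  profiles <- lapply(seq_len(nrow(meta)), function(i) {
    m <- meta[i, ]
    o <- obs[obs$profile_id == m$profile_id, , drop = FALSE]
    if (nrow(o) == 0) stop("profile ", m$profile_id, " has no observations")
    o <- o[order(o$time_min), , drop = FALSE]
    dd <- dos[dos$profile_id == m$profile_id, , drop = FALSE]
    bas <- dd[dd$kind == "basal", , drop = FALSE]
    bol <- dd[dd$kind == "bolus", , drop = FALSE]
    sched <- dosing_schedule(
      basal = if (nrow(bas)) data.frame(start = bas$start_min,
                                        end = bas$end_min_or_duration,
                                        rate = bas$amount),
      bolus = if (nrow(bol)) data.frame(start = bol$start_min,
                                        duration = bol$end_min_or_duration,
                                        dose = bol$amount))
    pk_profile(m$woman, m$visit, m$meal, o$time_min, o$concentration_pmol_l,
               sched, m$weight_kg, m$t_end_min, m$t_start_min,
               m$unit_conversion)
  })
  ord <- order(meta$woman, meta$visit, meta$meal)
  profiles <- profiles[ord]
  design <- NULL
  if (file.exists(file.path(dir, "covariates.tsv"))) {
    cov <- rd("covariates.tsv"); sch <- rd("covariate_types.tsv")
    cov <- cov[match(vapply(profiles, `[[`, character(1), "profile_id"),
                     cov$profile_id), , drop = FALSE]
    inter <- sch$factor[sch$type == "interaction"]
    plain <- sch[sch$type != "interaction", , drop = FALSE]
    design <- build_design(cov, setNames(plain$type, plain$factor),
                           study_col = NULL, meal_col = NULL)
    if (length(inter)) {
      XI <- as.matrix(cov[inter])
      rownames(XI) <- cov$profile_id
      design$X <- cbind(design$X, XI)
      design$group <- c(design$group, rep("interaction", length(inter)))
      design$center <- c(design$center, setNames(rep(0, length(inter)), inter))
      design$scale <- c(design$scale, setNames(rep(1, length(inter)), inter))
    }
  }
  excluded <- character()
  if (file.exists(file.path(dir, "excluded.tsv"))) {
    ex <- rd("excluded.tsv")
    excluded <- setNames(ex$reason, ex$profile_id)
  }
  pk_dataset(profiles, design, excluded)
}
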