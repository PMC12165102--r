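#' Construct a single diet composition
#'
#' A diet is described by the fractions of metabolizable energy supplied by
#' protein, carbohydrate and fat (which must close to 1 on the simplex),
#' together with the energy density of the dry food.
#'
#' @param label Short unique diet label.
#' @param protein,carb,fat Macronutrient energy fractions in `[0, 1]`,
#'   summing to 1 within `1e-8`.
#' @param energy_density Energy density in MJ per kg dry food (> 0).
#' @return A one-row data frame of class `diet_design` with columns
#'   `label`, `protein`, `carb`, `fat`, `energy_density`.
#' @export
#' @examples
#' diet_composition("HF", 0.05, 0.20, 0.75)
diet_composition <- function(label, protein, carb, fat, energy_density = 14.5) {
  d <- data.frame(label = as.character(label),
                  protein = as.numeric(protein),
                  carb = as.numeric(carb),
                  fat = as.numeric(fat),
                  energy_density = as.numeric(energy_density),
                  stringsAsFactors = FALSE)
  class(d) <- c("diet_design", "data.frame")
  validate_diet_design(d, require_shared_density = FALSE)
  d
}

#' Assemble a diet design from compositions
#'
#' @param ... One-row `diet_design` objects or data frames with the
#'   `diet_design` columns, stacked in order.
#' @param shared_energy_density If not `NULL`, every diet must have this
#'   energy density (an isocaloric design).
#' @return A `diet_design` data frame.
#' @export
diet_design <- function(..., shared_energy_density = NULL) {
  d <- do.call(rbind, lapply(list(...), as.data.frame))
  class(d) <- c("diet_design", "data.frame")
  rownames(d) <- NULL
  validate_diet_design(d, require_shared_density = !is.null(shared_energy_density),
                       shared_energy_density = shared_energy_density)
  d
}

# Closure, bound and uniqueness checks shared by all constructors/readers.
validate_diet_design <- function(d, require_shared_density = TRUE,
                                 shared_energy_density = NULL, tol = 1e-8) {
  needed <- c("label", "protein", "carb", "fat", "energy_density")
  missing <- setdiff(needed, names(d))
  if (length(missing))
    stop("diet design is missing column(s): ", paste(missing, collapse = ", "))
  if (nrow(d) < 1L) stop("diet design must contain at least one diet")
  fr <- as.matrix(d[, c("protein", "carb", "fat")])
  if (!all(is.finite(fr))) stop("non-finite macronutrient fraction")
  if (any(fr < -tol)) stop("macronutrient fractions must be >= 0")
  bad <- which(abs(rowSums(fr) - 1) > tol)
  if (length(bad))
    stop("fractions do not sum to 1 within 1e-8 for diet(s): ",
         paste(d$label[bad], collapse = ", "))
  if (any(!is.finite(d$energy_density)) || any(d$energy_density <= 0))
    stop("energy_density must be positive and finite")
  if (anyDuplicated(d$label))
    stop("diet labels must be unique; duplicated: ",
         paste(unique(d$label[duplicated(d$label)]), collapse = ", "))
  if (require_shared_density) {
    target <- if (is.null(shared_energy_density)) d$energy_density[1] else shared_energy_density
    if (any(abs(d$energy_density - target) > tol))
      stop("design is not isocaloric: energy densities differ")
  }
  invisible(d)
}

#' Apex diets of the isocaloric macronutrient array
#'
#' Returns the three macronutrient-apex diets -- high protein (HP, P:C:F =
#' 60:20:20), high carbohydrate (HC, 5:75:20) and high fat (HF, 5:20:75) --
#' plus the AIN-93G growth reference diet (20:64:16), all at the shared
#' energy density of 14.5 MJ/kg.
#'
#' @return A `diet_design` with four rows labelled `HP`, `HC`, `HF`,
#'   `AIN93G`.
#' @export
#' @examples
#' make_apex_diets()
make_apex_diets <- function() {
  d <- data.frame(
    label = c("HP", "HC", "HF", "AIN93G"),
    protein = c(0.60, 0.05, 0.05, 0.20),
    carb    = c(0.20, 0.75, 0.20, 0.64),
    fat     = c(0.20, 0.20, 0.75, 0.16),
    energy_density = 14.5,
    stringsAsFactors = FALSE)
  class(d) <- c("diet_design", "data.frame")
  validate_diet_design(d)
  d
}

# Feasible window of the design region (energy percent).
design_bounds <- function() {
  list(protein = c(5, 60), carb = c(20, 75), fat = c(20, 75))
}

#' Generate a space-filling isocaloric diet design
#'
#' Builds an array of `n_diets` isocaloric diets spanning the macronutrient
#' window 5--60% protein, 20--75% carbohydrate and 20--75% fat. The three
#' apex diets (HP, HC, HF) are always included; the remaining diets are
#' chosen by a seeded maximin greedy selection from a Latin-hypercube cloud
#' restricted to the feasible simplex window, so the interior fills the
#' design region as evenly as possible.
#'
#' @param n_diets Total number of diets (>= 4). Default 10.
#' @param seed Integer seed; the design is deterministic given the seed.
#' @param energy_density Shared energy density, MJ/kg.
#' @return A `diet_design` with `n_diets` rows; rows 1--3 are HP, HC, HF.
#' @export
#' @examples
#' d <- make_full_design(10, seed = 1)
#' range(d$protein)
make_full_design <- function(n_diets = 10, seed, energy_density = 14.5) {
  if (!is.numeric(n_diets) || n_diets < 4)
    stop("n_diets must be at least 4 (three apex diets plus interior)")
  if (missing(seed)) stop("seed is required")
  n_diets <- as.integer(n_diets)
  apex <- make_apex_diets()[1:3, ]
  n_int <- n_diets - 3L

  bounds <- design_bounds()
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(as.integer(seed))

  # Candidate cloud in the (protein, fat) rectangle, filtered to the
  # carbohydrate window; greedy maximin against already-chosen points.
  cloud <- lhs::randomLHS(600, 2)
  p <- bounds$protein[1] / 100 + cloud[, 1] * diff(bounds$protein) / 100
  f <- bounds$fat[1] / 100 + cloud[, 2] * diff(bounds$fat) / 100
  c_ <- 1 - p - f
  keep <- c_ >= bounds$carb[1] / 100 & c_ <= bounds$carb[2] / 100
  cand <- cbind(p, f)[keep, , drop = FALSE]
  chosen <- as.matrix(apex[, c("protein", "fat")])
  picked <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(n_int)) {
    dmin <- apply(cand, 1, function(q)
      min(sqrt(rowSums((rbind(chosen, picked) - matrix(q, nrow(chosen) + nrow(picked), 2, byrow = TRUE))^2))))
    j <- which.max(dmin)
    picked <- rbind(picked, cand[j, ])
    cand <- cand[-j, , drop = FALSE]
  }
  interior <- data.frame(
    label = sprintf("D%02d", seq_len(n_int) + 3L),
    protein = picked[, 1],
    carb = 1 - picked[, 1] - picked[, 2],
    fat = picked[, 2],
    energy_density = energy_density,
    stringsAsFactors = FALSE)
  apex$energy_density <- energy_density
  d <- rbind(as.data.frame(apex), interior)
  class(d) <- c("diet_design", "data.frame")
  rownames(d) <- NULL
  validate_diet_design(d)
  d
}

#' Classify a diet as ketogenic
#'
#' A diet is ketogenic when its carbohydrate content falls strictly below
#' the threshold share of total energy (default 10%).
#'
#' @param diet A `diet_design` (any number of rows).
#' @param threshold Carbohydrate energy-fraction threshold in (0, 1).
#' @return Logical vector, one flag per diet row.
#' @export
#' @examples
#' classify_ketogenic(make_apex_diets())  # none: HF carb is 20%
classify_ketogenic <- function(diet, threshold = 0.10) {
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= 0 || threshold >= 1)
    stop("threshold must be a single value in (0, 1)")
  validate_diet_design(diet, require_shared_density = FALSE)
  diet$carb < threshold
}

#' Read a diet design from CSV
#'
#' Expects columns `label,protein_pct,carb_pct,fat_pct,energy_density_mj_kg`
#' with macronutrients in percent of energy; percentages are normalized to
#' fractions and simplex closure is validated at `1e-8`.
#'
#' @param path CSV file path.
#' @return A `diet_design`.
#' @export
#' @examples
#' read_diet_design(system.file("extdata", "apex_diets.csv",
#'                              package = "nutrigeom"))
read_diet_design <- function(path) {
  d <- read_checked_csv(path,
    c("label", "protein_pct", "carb_pct", "fat_pct", "energy_density_mj_kg"),
    numeric_cols = c("protein_pct", "carb_pct", "fat_pct", "energy_density_mj_kg"))
  out <- data.frame(label = as.character(d$label),
                    protein = d$protein_pct / 100,
                    carb = d$carb_pct / 100,
                    fat = d$fat_pct / 100,
                    energy_density = d$energy_density_mj_kg,
                    stringsAsFactors = FALSE)
  class(out) <- c("diet_design", "data.frame")
  validate_diet_design(out, require_shared_density = FALSE)
  out
}

#' Write a diet design to CSV
#'
#' @param design A `diet_design`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_diet_design <- function(design, path) {
  validate_diet_design(design, require_shared_density = FALSE)
  out <- data.frame(label = design$label,
                    protein_pct = design$protein * 100,
                    carb_pct = design$carb * 100,
                    fat_pct = design$fat * 100,
                    energy_density_mj_kg = design$energy_density)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
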