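#' Compound parameter sets
#'
#' A `compound_params` object holds the physicochemical and ADME parameters
#' the simulation engine needs for one drug: binding (`fu_plasma`, blood
#' partitioning), absorption (`fa`, `ka`, `fu_gut`), enzyme-specific unbound
#' intrinsic clearances for hepatic and gut-wall CYP3A4/CYP3A5, renal blood
#' clearance, and lumped two-compartment disposition (`vss`, `k12`, `k21`).
#' Perpetrator drugs additionally carry unbound competitive inhibition
#' constants `ki_cyp3a4` and `ki_cyp3a5` (ng/mL).
#'
#' Intrinsic clearances are expressed per unit *relative* enzyme abundance:
#' an abundance of 1 is the population reference expressor level, so genotype
#' and graft-function scenarios act as pure multipliers.
#'
#' @param name Compound name.
#' @param molecular_weight Molecular weight, g/mol.
#' @param fu_plasma Unbound fraction in plasma, in (0, 1].
#' @param bp_ratio_ref Blood-to-plasma concentration ratio at `hct_ref`.
#' @param hct_ref Reference hematocrit fraction for `bp_ratio_ref`.
#' @param fa Fraction of an oral dose reaching the gut wall, in (0, 1].
#' @param ka First-order absorption rate constant, 1/h.
#' @param fu_gut Unbound fraction in the enterocyte, in (0, 1].
#' @param clint_cyp3a4_liver,clint_cyp3a5_liver Unbound hepatic intrinsic
#'   clearance at reference abundance, L/h.
#' @param clint_cyp3a4_gut,clint_cyp3a5_gut Unbound gut-wall intrinsic
#'   clearance at reference abundance, L/h.
#' @param cl_renal Renal blood clearance, L/h.
#' @param vss Steady-state volume of distribution referenced to whole blood
#'   at `hct_ref`, L/kg.
#' @param k12,k21 Inter-compartment distribution rate constants, 1/h.
#' @param ki_cyp3a4,ki_cyp3a5 Unbound competitive inhibition constants,
#'   ng/mL; `NULL` for drugs never used as perpetrators.
#' @return A validated `compound_params` object.
#' @seealso [load_compound()], [blood_partition()]
#' @export
compound_params <- function(name, molecular_weight, fu_plasma, bp_ratio_ref,
                            hct_ref = 0.45, fa, ka, fu_gut,
                            clint_cyp3a4_liver, clint_cyp3a5_liver,
                            clint_cyp3a4_gut, clint_cyp3a5_gut,
                            cl_renal = 0, vss, k12 = 0, k21 = 0,
                            ki_cyp3a4 = NULL, ki_cyp3a5 = NULL) {
  x <- list(
    name = name, molecular_weight = molecular_weight,
    fu_plasma = fu_plasma, bp_ratio_ref = bp_ratio_ref, hct_ref = hct_ref,
    fa = fa, ka = ka, fu_gut = fu_gut,
    clint_cyp3a4_liver = clint_cyp3a4_liver,
    clint_cyp3a5_liver = clint_cyp3a5_liver,
    clint_cyp3a4_gut = clint_cyp3a4_gut,
    clint_cyp3a5_gut = clint_cyp3a5_gut,
    cl_renal = cl_renal, vss = vss, k12 = k12, k21 = k21,
    ki_cyp3a4 = ki_cyp3a4, ki_cyp3a5 = ki_cyp3a5
  )
  class(x) <- "compound_params"
  validate_compound(x)
}

validate_compound <- function(x) {
  fail <- function(field, why) {
    abort(sprintf("Invalid compound parameter `%s`: %s.", field, why),
          class = "tacswitch_validation_error")
  }
  num1 <- function(field) {
    v <- x[[field]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      fail(field, "must be a single finite number")
    }
    v
  }
  if (!is.character(x$name) || length(x$name) != 1L || !nzchar(x$name)) {
    fail("name", "must be a non-empty string")
  }
  for (f in c("fu_plasma", "fa", "fu_gut")) {
    v <- num1(f)
    if (v <= 0 || v > 1) fail(f, "must be a fraction in (0, 1]")
  }
  for (f in c("clint_cyp3a4_liver", "clint_cyp3a5_liver", "clint_cyp3a4_gut",
              "clint_cyp3a5_gut", "cl_renal", "k12", "k21")) {
    if (num1(f) < 0) fail(f, "must be >= 0")
  }
  for (f in c("molecular_weight", "bp_ratio_ref", "vss", "ka")) {
    if (num1(f) <= 0) fail(f, "must be > 0")
  }
  v <- num1("hct_ref")
  if (v <= 0.1 || v >= 0.6) fail("hct_ref", "must lie in (0.1, 0.6)")
  for (f in c("ki_cyp3a4", "ki_cyp3a5")) {
    if (!is.null(x[[f]]) && (num1(f) <= 0)) fail(f, "must be > 0 when present")
  }
  if (xor(is.null(x$ki_cyp3a4), is.null(x$ki_cyp3a5))) {
    fail("ki_cyp3a5", "perpetrators need both ki_cyp3a4 and ki_cyp3a5")
  }
  x
}

#' Is a compound usable as a perpetrator?
#'
#' @param compound A `compound_params` object.
#' @return `TRUE` if both inhibition constants are present.
#' @export
is_perpetrator <- function(compound) {
  !is.null(compound$ki_cyp3a4) && !is.null(compound$ki_cyp3a5)
}

builtin_compound_path <- function(name) {
  system.file("extdata", "compounds", paste0(name, ".yaml"),
              package = "tacswitch")
}

#' Load a compound parameter set
#'
#' Loads one of the built-in parameter sets (`"tacrolimus"`,
#' `"itraconazole"`) or a flat key-value YAML/JSON file with the fields of
#' [compound_params()]. Every built-in default is traceable to the literature
#' or to the package's calibration; see [compound_provenance()]. Individual
#' fields can be replaced through `overrides`, and the result is re-validated.
#'
#' @param name Built-in compound name or path to a parameter file.
#' @param overrides Named list of field values replacing the file's defaults.
#' @return A validated `compound_params` object.
#' @examples
#' tac <- load_compound("tacrolimus")
#' tac$cl_renal
#' fast <- load_compound("tacrolimus", overrides = list(ka = 1.5))
#' @export
load_compound <- function(name, overrides = list()) {
  path <- if (file.exists(name)) name else builtin_compound_path(name)
  if (!nzchar(path) || !file.exists(path)) {
    abort(sprintf(
      "Unknown compound '%s': not a built-in compound and not a file.", name
    ))
  }
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (length(overrides)) {
    if (is.null(names(overrides)) || any(!nzchar(names(overrides)))) {
      abort("`overrides` must be a fully named list.")
    }
    unknown <- setdiff(names(overrides), names(formals(compound_params)))
    if (length(unknown)) {
      abort(sprintf("Unknown compound field(s) in overrides: %s.",
                    paste(unknown, collapse = ", ")))
    }
    raw <- modifyList(raw, overrides)
  }
  do.call(compound_params, raw)
}

#' Write a compound parameter set to a YAML file
#'
#' The written file round-trips: [load_compound()] on the result reproduces
#' every field exactly.
#'
#' @param compound A `compound_params` object.
#' @param path Output file path (YAML).
#' @return `path`, invisibly.
#' @export
write_compound <- function(compound, path) {
  stopifnot(inherits(compound, "compound_params"))
  x <- compound[!vapply(compound, is.null, logical(1))]
  yaml::write_yaml(x, path, precision = 17L)
  invisible(path)
}

#' Hematocrit-dependent blood partitioning
#'
#' Rescales a compound's reference blood-to-plasma ratio to an individual's
#' hematocrit assuming a fixed red-cell-to-plasma partition coefficient
#' `K_rbc = (bp_ratio_ref - (1 - hct_ref)) / hct_ref`:
#' `B:P(h) = (1 - h) + h * K_rbc`. The unbound blood fraction follows as
#' `fu_blood = fu_plasma / B:P(h)`, so `fu_blood * B:P = fu_plasma` exactly.
#' For a red-cell-partitioned drug like tacrolimus (`bp_ratio_ref` well above
#' 1) a drop in hematocrit lowers B:P and raises the unbound blood fraction,
#' which is how anemia feeds into hepatic clearance here.
#'
#' @param compound A `compound_params` object.
#' @param hematocrit Hematocrit fraction, in (0.1, 0.6).
#' @return A list with `bp_ratio` and `fu_blood`.
#' @examples
#' tac <- load_compound("tacrolimus")
#' blood_partition(tac, 0.237)$bp_ratio  # 8.374 at the reference B:P of 15
#' @export
blood_partition <- function(compound, hematocrit) {
  if (!is.numeric(hematocrit) || length(hematocrit) != 1L ||
      hematocrit <= 0.1 || hematocrit >= 0.6) {
    abort("`hematocrit` must be a single fraction in (0.1, 0.6).")
  }
  k_rbc <- (compound$bp_ratio_ref - (1 - compound$hct_ref)) / compound$hct_ref
  bp <- (1 - hematocrit) + hematocrit * k_rbc
  list(bp_ratio = bp, fu_blood = compound$fu_plasma / bp)
}

#' Provenance of the built-in compound parameters
#'
#' One row per built-in parameter value with the source it was taken from or
#' the calibration rule that fixed it.
#'
#' @return A tibble with columns `compound`, `field`, `value`, `units`,
#'   `source`.
#' @export
compound_provenance <- function() {
  path <- system.file("extdata", "compound_provenance.csv",
                      package = "tacswitch")
  as_tibble(utils::read.csv(path, check.names = FALSE))
}

#' @export
print.compound_params <- function(x, ...) {
  cat(sprintf("<compound_params: %s>\n", x$name))
  flds <- x[setdiff(names(x), "name")]
  flds <- flds[!vapply(flds, is.null, logical(1))]
  for (f in names(flds)) cat(sprintf("  %-20s %g\n", f, flds[[f]]))
  if (!is_perpetrator(x)) cat("  (no Ki values: victim only)\n")
  invisible(x)
}

#' @export
as_tibble.compound_params <- function(x, ...) {
  flds <- x[!vapply(x, is.null, logical(1))]
  as_tibble(flds)
}
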