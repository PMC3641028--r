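# Chemostat steady-state arithmetic. At steady state the specific growth
# rate mu equals the dilution rate D, and all measured rates are specific
# fluxes in mmolC/gDW/h, so yields, carbon balances and alginate efficiencies
# follow from simple ratios.

OD660_TO_GDW_PER_L <- 0.36   # biomass conversion factor, g/L per OD660 unit
CARBON_MOLAR_MASS <- 12.011  # g/mol

#' Create a chemostat steady-state record
#'
#' One strain x carbon-source steady state: dilution rate (equal to the
#' specific growth rate), culture density and the measured specific carbon
#' fluxes. Unmeasured channels ("-" entries in a data table) enter as 0.
#'
#' @param strain Strain label.
#' @param carbon_source `"fructose"` or `"glycerol"`.
#' @param dilution_rate D in 1/h (> 0).
#' @param od660 Optical density at 660 nm.
#' @param q_uptake,q_alginate,q_acetyl,q_co2,q_biomass_c Specific rates in
#'   mmolC/gDW/h (all >= 0): carbon-source uptake, deacetylated alginate
#'   production, acetyl (from alginate) release, CO2 excretion and carbon
#'   fixed in biomass.
#' @return A list of class `"chemostat_record"`.
#' @export
chemostat_record <- function(strain, carbon_source, dilution_rate, od660,
                             q_uptake, q_alginate = 0, q_acetyl = 0,
                             q_co2 = 0, q_biomass_c = 0) {
  carbon_source <- match.arg(carbon_source, c("fructose", "glycerol"))
  if (dilution_rate <= 0) stop("dilution_rate must be positive")
  q <- c(q_uptake = q_uptake, q_alginate = q_alginate, q_acetyl = q_acetyl,
         q_co2 = q_co2, q_biomass_c = q_biomass_c)
  if (any(q < 0)) {
    stop("negative specific rate(s): ",
         paste(names(q)[q < 0], collapse = ", "))
  }
  if (od660 < 0) stop("od660 must be non-negative")
  structure(c(list(strain = strain, carbon_source = carbon_source,
                   dilution_rate = dilution_rate, od660 = od660),
              as.list(q)),
            class = "chemostat_record")
}

#' Read a table of chemostat records
#'
#' Tab-separated file with columns `strain`, `carbon_source`,
#' `dilution_rate`, `od660`, `q_uptake`, `q_alginate`, `q_acetyl`, `q_co2`,
#' `q_biomass_c` (and optionally `c_balance_printed` carried along as an
#' annotation). The packaged steady-state table of the five SBW25 strains is
#' at `system.file("extdata", "sbw25_chemostat.tsv", package = "mucaflux")`.
#'
#' @param path TSV file path.
#' @return A data frame with one row per record and class
#'   `"chemostat_table"`.
#' @export
read_chemostat_records <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("strain", "carbon_source", "dilution_rate", "od660", "q_uptake",
            "q_alginate", "q_acetyl", "q_co2", "q_biomass_c")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("chemostat table ", path, " lacks columns: ",
         paste(missing, collapse = ", "))
  }
  class(df) <- c("chemostat_table", "data.frame")
  df
}

.as_record <- function(x) {
  if (inherits(x, "chemostat_record")) return(x)
  chemostat_record(x$strain, x$carbon_source, x$dilution_rate, x$od660,
                   x$q_uptake, x$q_alginate, x$q_acetyl, x$q_co2,
                   x$q_biomass_c)
}

#' Biomass concentration from optical density
#'
#' @param od660 Optical density at 660 nm (>= 0).
#' @return Biomass concentration in gDW/L (0.36 g/L per OD unit).
#' @export
biomass_concentration <- function(od660) {
  if (any(od660 < 0)) stop("od660 must be non-negative")
  OD660_TO_GDW_PER_L * od660
}

#' Biomass yield of a chemostat steady state
#'
#' At steady state mu = D, so the yield is D divided by the substrate mass
#' uptake rate; the measured uptake in mmolC/gDW/h is converted to g/gDW/h
#' through the substrate molar mass and carbon count.
#'
#' @param record A `chemostat_record` (or one row of a chemostat table).
#' @param source Optional [carbon_source()]; defaults to the record's own.
#' @param digits Rounding of the reported yield (default 2, the precision of
#'   the source data).
#' @return Yield in g-DW per g-substrate.
#' @export
biomass_yield <- function(record, source = NULL, digits = 2) {
  record <- .as_record(record)
  if (record$q_uptake <= 0) {
    stop("biomass_yield undefined: record '", record$strain,
         "' has zero substrate uptake")
  }
  if (is.null(source)) source <- carbon_source(record$carbon_source)
  g_per_h <- record$q_uptake * source$molar_mass /
    (1000 * source$carbon_atoms)
  round(record$dilution_rate / g_per_h, digits)
}

#' Carbon balance of a chemostat steady state
#'
#' Percentage of imported carbon recovered in the measured product channels
#' (alginate, acetyl, CO2 and biomass).
#'
#' @param record A `chemostat_record`.
#' @param digits Rounding (default 1).
#' @return Carbon balance in percent.
#' @export
carbon_balance <- function(record, digits = 1) {
  record <- .as_record(record)
  if (record$q_uptake <= 0) {
    stop("carbon_balance undefined: zero substrate uptake")
  }
  out <- record$q_alginate + record$q_acetyl + record$q_co2 +
    record$q_biomass_c
  round(100 * out / record$q_uptake, digits)
}

#' Fraction of imported carbon channelled into alginate
#'
#' Counts both the polymer backbone and the acetyl groups it carries.
#'
#' @param record A `chemostat_record`.
#' @return Percent of imported carbon in alginate, rounded to an integer.
#' @export
alginate_carbon_fraction <- function(record) {
  record <- .as_record(record)
  if (record$q_uptake <= 0) {
    stop("alginate_carbon_fraction undefined: zero substrate uptake")
  }
  round(100 * (record$q_alginate + record$q_acetyl) / record$q_uptake)
}

#' Alginate biosynthesis efficiency relative to a reference strain
#'
#' The substrate actually available for alginate production is estimated by
#' subtracting, from the producer's uptake, the uptake of the
#' non-alginate-producing strain with the highest biomass yield on the same
#' carbon source (the most carbon the organism is observed to channel into
#' biomass). The molar monomer yield is then computed on the remaining
#' carbon: (q_alginate / 6) / (available_C / substrate carbon count). Acetyl
#' carbon is not part of the 6-carbon monomer skeleton and is excluded from
#' the numerator.
#'
#' @param producer Alginate-producing `chemostat_record`.
#' @param reference Non-producing reference record on the same carbon source.
#' @param source Optional [carbon_source()]; defaults to the producer's.
#' @param digits Rounding (default 2).
#' @return Efficiency in mmol monomer per mmol substrate.
#' @export
alginate_efficiency <- function(producer, reference, source = NULL,
                                digits = 2) {
  producer <- .as_record(producer)
  reference <- .as_record(reference)
  if (!identical(producer$carbon_source, reference$carbon_source)) {
    stop("producer and reference must share a carbon source")
  }
  if (is.null(source)) source <- carbon_source(producer$carbon_source)
  available_c <- producer$q_uptake - reference$q_uptake
  if (available_c <= 0) {
    stop("no carbon available for alginate: reference uptake (",
         reference$q_uptake, ") >= producer uptake (", producer$q_uptake,
         ")")
  }
  round((producer$q_alginate / 6) / (available_c / source$carbon_atoms),
        digits)
}

#' Respiration ratio between two steady states
#'
#' @param a,b `chemostat_record`s; the ratio is a's CO2 excretion over b's.
#' @param digits Rounding (default 2).
#' @return Dimensionless ratio of specific CO2 excretion rates.
#' @export
respiration_ratio <- function(a, b, digits = 2) {
  a <- .as_record(a); b <- .as_record(b)
  if (b$q_co2 <= 0) stop("respiration_ratio undefined: zero reference CO2")
  round(a$q_co2 / b$q_co2, digits)
}

#' Specific biomass carbon flux at a given growth rate
#'
#' @param mu Specific growth rate in 1/h.
#' @param carbon_fraction Cellular carbon content in gC/gDW (the core model's
#'   calibration is 0.4534, i.e. 37.75 mmolC/gDW).
#' @return Biomass carbon flux in mmolC/gDW/h.
#' @export
biomass_carbon_flux <- function(mu,
                                carbon_fraction =
                                  BIOMASS_CARBON_MMOL_PER_G *
                                  CARBON_MOLAR_MASS / 1000) {
  if (any(mu < 0) || any(carbon_fraction < 0)) {
    stop("mu and carbon_fraction must be non-negative")
  }
  1000 * mu * carbon_fraction / CARBON_MOLAR_MASS
}

#' Summarize a table of chemostat records
#'
#' @param records A `chemostat_table` (from [read_chemostat_records()]) or a
#'   data frame with the same columns.
#' @return Data frame with strain, carbon source, biomass concentration and
#'   yield, carbon balance and alginate carbon fraction per record.
#' @export
physiology_summary <- function(records) {
  rows <- lapply(seq_len(nrow(records)), function(i) {
    r <- .as_record(records[i, ])
    data.frame(strain = r$strain,
               carbon_source = r$carbon_source,
               biomass_g_per_l = biomass_concentration(r$od660),
               biomass_yield = biomass_yield(r),
               carbon_balance = carbon_balance(r),
               alginate_fraction = alginate_carbon_fraction(r),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
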