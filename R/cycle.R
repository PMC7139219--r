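## The thermodynamic cycle of lipoprotein transfer through the Lol pathway.

#' Build the transfer thermodynamic cycle from extraction free energies
#'
#' Combines the four extraction free energies of the cysteine-lipid moiety
#' (the cost of removing it from the inner membrane, the LolA cavity, the
#' LolB cavity or the outer membrane into water) into the three transfer
#' steps by pairwise subtraction:
#' step1 = IM - LolA (extraction from the inner membrane into the LolA
#' complex), step2 = LolA - LolB, step3 = LolB - OM. Positive values are
#' energy the cell must supply for that hop; the net cost of one full
#' transfer is the exact sum of the steps (equivalently IM - OM).
#'
#' @param energies named numeric: IM, LolA, LolB, OM (kJ/mol, each >= 0)
#' @param errors optional named standard errors on the energies (kJ/mol);
#'   step errors are combined in quadrature
#' @param moiety "triacyl" or "diacyl"
#' @return a \linkS4class{TransferCycle}
#' @examples
#' buildCycle(c(IM = 115, LolA = 50, LolB = 62, OM = 112))
#' @export
buildCycle <- function(energies, errors = NULL,
                       moiety = c("triacyl", "diacyl")) {
  moiety <- match.arg(moiety)
  need <- c("IM", "LolA", "LolB", "OM")
  if (!all(need %in% names(energies)))
    stop("energies must be named IM, LolA, LolB, OM", call. = FALSE)
  e <- energies[need]
  if (any(!is.finite(e))) stop("energies must be finite", call. = FALSE)
  if (any(e < 0)) stop("extraction free energies must be >= 0",
                       call. = FALSE)
  steps <- c(IM_to_LolA = unname(e["IM"] - e["LolA"]),
             LolA_to_LolB = unname(e["LolA"] - e["LolB"]),
             LolB_to_OM = unname(e["LolB"] - e["OM"]))
  err <- if (is.null(errors)) stats::setNames(rep(NA_real_, 4), need)
         else errors[need]
  stepErr <- c(IM_to_LolA = sqrt(err[["IM"]]^2 + err[["LolA"]]^2),
               LolA_to_LolB = sqrt(err[["LolA"]]^2 + err[["LolB"]]^2),
               LolB_to_OM = sqrt(err[["LolB"]]^2 + err[["OM"]]^2))
  new("TransferCycle", energies = e, steps = steps,
      net = sum(steps), errors = err, stepErrors = stepErr,
      moiety = moiety)
}

#' ATP budget feasibility of the membrane-extraction step
#'
#' Compares the uphill first step of the cycle (extraction from the inner
#' membrane into the LolA complex) against the free energy released by ATP
#' hydrolysis. Physiological per-ATP release spans roughly 31.55 to 46.5
#' kJ/mol; the inner-membrane ABC transporter hydrolyses two ATP per
#' transfer, giving a default budget interval of 63.1 to 93.0 kJ/mol.
#'
#' @param cycle a \linkS4class{TransferCycle}
#' @param perATPRange magnitude of the per-ATP free-energy release interval
#'   (kJ/mol)
#' @param nATP ATP molecules hydrolysed per transfer (>= 1)
#' @return list: step1, budget (kJ/mol interval), feasibleAtUpper,
#'   feasibleAtLower, marginal (feasible only at part of the range)
#' @export
atpFeasibility <- function(cycle, perATPRange = c(31.55, 46.5), nATP = 2L) {
  stopifnot(is(cycle, "TransferCycle"), nATP >= 1L)
  budget <- sort(abs(perATPRange)) * nATP
  step1 <- cycle@steps[["IM_to_LolA"]]
  lower <- step1 <= budget[1]
  upper <- step1 <= budget[2]
  list(step1 = step1, budget = budget, nATP = as.integer(nATP),
       feasibleAtLower = lower, feasibleAtUpper = upper,
       marginal = upper && !lower)
}

#' Read extraction energies from TSV or JSON
#'
#' TSV needs columns environment, energy (optionally error); JSON is a named
#' object of energies (optionally an object with energy/error per name).
#'
#' @param path input file; format by extension (.json otherwise TSV)
#' @return list with energies and errors (named numerics)
#' @export
readExtractionEnergies <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (is.list(x) && !is.null(x$energy))
      return(list(energies = unlist(x$energy), errors = unlist(x$error)))
    return(list(energies = unlist(x), errors = NULL))
  }
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  list(energies = stats::setNames(df$energy, df$environment),
       errors = if ("error" %in% names(df))
         stats::setNames(df$error, df$environment) else NULL)
}

#' Write a transfer cycle report as JSON
#'
#' @param cycle a \linkS4class{TransferCycle}
#' @param path output file
#' @export
writeCycleJSON <- function(cycle, path) {
  jsonlite::write_json(
    list(moiety = cycle@moiety,
         energies = as.list(cycle@energies),
         steps = as.list(cycle@steps),
         net = cycle@net),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
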