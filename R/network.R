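#' Construct an evidence network of arm-level event data
#'
#' An evidence network bundles a treatment coding table with arm-level trial
#' summaries in one or both of the two reporting formats used for adverse
#' events such as severe hypoglycaemia:
#' \describe{
#'   \item{risk}{number of patients with at least one event (\code{r}) out of
#'     patients randomised (\code{n}), over a stated follow-up (years);}
#'   \item{rate}{total number of events (\code{y}) over total person-years of
#'     exposure (\code{person_years}), allowing repeat events per patient.}
#' }
#' A study may contribute records in both formats (then both must cover the
#' same treatments); the choice of which records enter a given analysis is
#' made by the fitting functions, not here.
#'
#' @param treatments data.frame with columns \code{code} (positive integers,
#'   contiguous from 1; code 1 is the network reference treatment) and
#'   \code{label}.
#' @param risk data.frame with columns \code{study_id}, \code{treatment_code},
#'   \code{r}, \code{n}, \code{followup} (years), or \code{NULL}.
#' @param rate data.frame with columns \code{study_id}, \code{treatment_code},
#'   \code{y}, \code{person_years}, or \code{NULL}.
#'
#' @return An object of class \code{evidence_network}: a list with elements
#'   \code{treatments}, \code{risk}, \code{rate} and \code{studies} (per-study
#'   metadata: reported formats and treatment set).
#' @export
evidence_network <- function(treatments, risk = NULL, rate = NULL) {
  treatments <- as.data.frame(treatments)
  if (!all(c("code", "label") %in% names(treatments))) {
    stop("schema error: treatments table needs columns 'code' and 'label'")
  }
  codes <- sort(as.integer(treatments$code))
  if (anyDuplicated(codes) || !identical(codes, seq_along(codes))) {
    stop("coding error: treatment codes must be unique and contiguous from 1")
  }
  treatments <- treatments[order(treatments$code), c("code", "label")]
  treatments$code <- as.integer(treatments$code)
  rownames(treatments) <- NULL

  risk <- validate_risk_table(risk, treatments$code)
  rate <- validate_rate_table(rate, treatments$code)
  if (nrow(risk) + nrow(rate) == 0L) stop("data error: no arm records supplied")

  studies <- build_study_index(risk, rate)
  structure(
    list(treatments = treatments, risk = risk, rate = rate, studies = studies),
    class = "evidence_network"
  )
}

empty_risk <- function() {
  data.frame(study_id = character(), treatment_code = integer(),
             r = integer(), n = integer(), followup = numeric(),
             stringsAsFactors = FALSE)
}

empty_rate <- function() {
  data.frame(study_id = character(), treatment_code = integer(),
             y = integer(), person_years = numeric(),
             stringsAsFactors = FALSE)
}

validate_risk_table <- function(risk, codes) {
  if (is.null(risk) || nrow(as.data.frame(risk)) == 0L) return(empty_risk())
  risk <- as.data.frame(risk)
  need <- c("study_id", "treatment_code", "r", "n", "followup")
  miss <- setdiff(need, names(risk))
  if (length(miss)) stop("schema error: risk table missing column(s): ",
                         paste(miss, collapse = ", "))
  risk <- risk[, need]
  risk$study_id <- as.character(risk$study_id)
  risk$treatment_code <- as.integer(risk$treatment_code)
  bad <- which(!(risk$treatment_code %in% codes))
  if (length(bad)) stop("coding error: unknown treatment code in risk row(s) ",
                        paste(bad, collapse = ", "))
  bad <- which(risk$n < 1 | risk$r < 0 | risk$r > risk$n)
  if (length(bad)) stop("data error: risk row(s) ", paste(bad, collapse = ", "),
                        " violate 0 <= r <= n, n >= 1")
  bad <- which(!(risk$followup > 0))
  if (length(bad)) stop("data error: risk row(s) ", paste(bad, collapse = ", "),
                        " have non-positive follow-up")
  fu <- tapply(risk$followup, risk$study_id, function(x) length(unique(x)))
  if (any(fu > 1)) stop("data error: follow-up differs across risk arms of study ",
                        paste(names(fu)[fu > 1], collapse = ", "))
  rownames(risk) <- NULL
  risk
}

validate_rate_table <- function(rate, codes) {
  if (is.null(rate) || nrow(as.data.frame(rate)) == 0L) return(empty_rate())
  rate <- as.data.frame(rate)
  need <- c("study_id", "treatment_code", "y", "person_years")
  miss <- setdiff(need, names(rate))
  if (length(miss)) stop("schema error: rate table missing column(s): ",
                         paste(miss, collapse = ", "))
  rate <- rate[, need]
  rate$study_id <- as.character(rate$study_id)
  rate$treatment_code <- as.integer(rate$treatment_code)
  bad <- which(!(rate$treatment_code %in% codes))
  if (length(bad)) stop("coding error: unknown treatment code in rate row(s) ",
                        paste(bad, collapse = ", "))
  bad <- which(rate$y < 0 | !(rate$person_years > 0))
  if (length(bad)) stop("data error: rate row(s) ", paste(bad, collapse = ", "),
                        " violate y >= 0, person_years > 0")
  rownames(rate) <- NULL
  rate
}

build_study_index <- function(risk, rate) {
  ids <- unique(c(risk$study_id, rate$study_id))
  out <- lapply(ids, function(id) {
    tr_risk <- sort(unique(risk$treatment_code[risk$study_id == id]))
    tr_rate <- sort(unique(rate$treatment_code[rate$study_id == id]))
    fmts <- c(if (length(tr_risk)) "risk", if (length(tr_rate)) "rate")
    if (length(tr_risk) && length(tr_rate) && !identical(tr_risk, tr_rate)) {
      stop("data error: study ", id,
           " reports both formats over different treatment sets")
    }
    trts <- if (length(tr_risk)) tr_risk else tr_rate
    if (length(trts) < 2) {
      stop("data error: study ", id, " has fewer than 2 distinct treatments")
    }
    list(study_id = id, treatments = trts, formats = fmts)
  })
  names(out) <- ids
  out
}

#' @export
print.evidence_network <- function(x, ...) {
  cat("Evidence network:", nrow(x$treatments), "treatments,",
      length(x$studies), "studies\n")
  n_both <- sum(vapply(x$studies, function(s) length(s$formats) == 2L, logical(1)))
  cat("  risk arms:", nrow(x$risk), " rate arms:", nrow(x$rate),
      " studies in both formats:", n_both, "\n")
  invisible(x)
}

#' Read an evidence network from delimited files
#'
#' Reads arm-level trial summaries and a treatment coding table from CSV
#' files. The risk schema is \code{study_id, treatment_code, r, n, followup,
#' followup_unit}; follow-up is converted to years from the per-row unit
#' (\code{weeks} at 52.18 weeks/year, \code{months} at 12 months/year, or
#' \code{years}). The rate schema is \code{study_id, treatment_code, y,
#' person_years}. The treatments file has columns \code{code, label}.
#'
#' @param path for \code{format = "risk"} or \code{"rate"}, the CSV file; for
#'   \code{"mixed"}, a named character vector \code{c(risk = ..., rate = ...)}
#'   (either element may be omitted).
#' @param treatments path to the treatment coding CSV.
#' @param format which reporting format(s) the file(s) contain.
#' @return A validated \code{\link{evidence_network}}; row order is preserved.
#' @examples
#' ex <- system.file("extdata", package = "eventnma")
#' net <- read_network(c(risk = file.path(ex, "risk.csv"),
#'                       rate = file.path(ex, "rate.csv")),
#'                     file.path(ex, "treatments.csv"))
#' net
#' summarize_network(net)$edges
#' @export
read_network <- function(path, treatments, format = c("mixed", "risk", "rate")) {
  format <- match.arg(format)
  for (f in c(unname(path), treatments)) {
    if (!file.exists(f)) stop("file not found: ", f)
  }
  trt <- utils::read.csv(treatments, stringsAsFactors = FALSE)
  risk <- rate <- NULL
  if (format == "risk") {
    risk <- read_risk_csv(path)
  } else if (format == "rate") {
    rate <- read_rate_csv(path)
  } else {
    if (is.null(names(path)) || !all(names(path) %in% c("risk", "rate"))) {
      stop("schema error: mixed format needs path = c(risk = ..., rate = ...)")
    }
    if ("risk" %in% names(path)) risk <- read_risk_csv(path[["risk"]])
    if ("rate" %in% names(path)) rate <- read_rate_csv(path[["rate"]])
  }
  evidence_network(trt, risk = risk, rate = rate)
}

read_risk_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("study_id", "treatment_code", "r", "n", "followup", "followup_unit")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("schema error: ", path, " missing column(s): ",
                         paste(miss, collapse = ", "))
  x$followup <- followup_to_years(x$followup, x$followup_unit)
  x$followup_unit <- NULL
  x
}

read_rate_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("study_id", "treatment_code", "y", "person_years")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("schema error: ", path, " missing column(s): ",
                         paste(miss, collapse = ", "))
  x
}

#' Convert follow-up durations to years
#'
#' @param x numeric durations.
#' @param unit per-element unit: \code{"weeks"}, \code{"months"} or
#'   \code{"years"} (52.18 weeks/year, 12 months/year).
#' @return durations in years.
#' @export
followup_to_years <- function(x, unit) {
  unit <- rep_len(as.character(unit), length(x))
  ok <- unit %in% c("weeks", "months", "years")
  if (!all(ok)) stop("schema error: unknown followup_unit: ",
                     paste(unique(unit[!ok]), collapse = ", "))
  x * ifelse(unit == "weeks", 1 / 52.18, ifelse(unit == "months", 1 / 12, 1))
}

#' Write an evidence network to delimited files
#'
#' Inverse of \code{\link{read_network}}: writes \code{risk.csv} (follow-up in
#' years, \code{followup_unit = "years"}), \code{rate.csv} and
#' \code{treatments.csv} into \code{dir}. Empty tables are skipped.
#'
#' @param network an \code{evidence_network}.
#' @param dir output directory (created if needed).
#' @return Invisibly, a named character vector of the files written.
#' @export
write_network <- function(network, dir) {
  stopifnot(inherits(network, "evidence_network"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  out <- c(treatments = file.path(dir, "treatments.csv"))
  utils::write.csv(network$treatments, out[["treatments"]], row.names = FALSE)
  if (nrow(network$risk)) {
    risk <- network$risk
    risk$followup_unit <- "years"
    out["risk"] <- file.path(dir, "risk.csv")
    utils::write.csv(risk, out[["risk"]], row.names = FALSE)
  }
  if (nrow(network$rate)) {
    out["rate"] <- file.path(dir, "rate.csv")
    utils::write.csv(network$rate, out[["rate"]], row.names = FALSE)
  }
  invisible(out)
}

# Studies (and their treatment sets) entering an analysis of the given format.
# "risk"/"rate": studies with records of that format. "shared": all studies,
# rate records preferred when a study reports both.
analysis_studies <- function(network, subset = c("mixed", "risk", "rate", "shared")) {
  subset <- match.arg(subset)
  keep <- switch(subset,
    mixed  = network$studies,
    risk   = Filter(function(s) "risk" %in% s$formats, network$studies),
    rate   = Filter(function(s) "rate" %in% s$formats, network$studies),
    shared = network$studies
  )
  keep
}

#' Connected components of the comparison graph
#'
#' Builds the comparison graph (nodes = treatments, edges = head-to-head
#' comparisons observed within studies) restricted to the studies entering an
#' analysis of the given format, and reports its connected components. A
#' single component containing every treatment certifies that all relative
#' effects are estimable in that analysis.
#'
#' @param network an \code{evidence_network}.
#' @param subset which analysis the graph is restricted to: \code{"mixed"}
#'   (all studies), \code{"risk"}, \code{"rate"}, or \code{"shared"} (all
#'   studies; same graph as \code{"mixed"}).
#' @return A list with \code{membership} (named integer vector, component id
#'   per treatment code), \code{n_components}, and \code{connected} (TRUE if
#'   all treatments fall in one component). Treatments absent from the subset
#'   form singleton components.
#' @export
validate_connectivity <- function(network, subset = "mixed") {
  stopifnot(inherits(network, "evidence_network"))
  studies <- analysis_studies(network, subset)
  nt <- nrow(network$treatments)
  edges <- integer(0)
  for (s in studies) {
    pr <- utils::combn(s$treatments, 2)
    edges <- c(edges, as.integer(pr))
  }
  g <- igraph::make_empty_graph(n = nt, directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  comp <- igraph::components(g)
  membership <- as.integer(comp$membership)
  names(membership) <- network$treatments$code
  list(membership = membership,
       n_components = comp$no,
       connected = comp$no == 1L)
}

#' Summarise a comparison network
#'
#' Per-treatment totals and per-comparison trial counts for the studies
#' entering an analysis, the quantities a network plot displays (node size
#' proportional to randomised patients, edge width to number of trials).
#'
#' @inheritParams validate_connectivity
#' @return A list of two data.frames: \code{nodes} (treatment code, label,
#'   \code{n_studies}, \code{patients} summed over risk arms,
#'   \code{person_years} summed over rate arms) and \code{edges} (treatment
#'   pair, number of trials with that direct comparison).
#' @export
summarize_network <- function(network, subset = "mixed") {
  stopifnot(inherits(network, "evidence_network"))
  studies <- analysis_studies(network, subset)
  ids <- names(studies)
  risk <- network$risk[network$risk$study_id %in% ids, , drop = FALSE]
  rate <- network$rate[network$rate$study_id %in% ids, , drop = FALSE]
  if (subset == "risk") rate <- empty_rate()
  if (subset == "rate") risk <- empty_risk()

  codes <- network$treatments$code
  nodes <- data.frame(
    code = codes,
    label = network$treatments$label,
    n_studies = vapply(codes, function(k) {
      sum(vapply(studies, function(s) k %in% s$treatments, logical(1)))
    }, integer(1)),
    patients = vapply(codes, function(k) {
      sum(risk$n[risk$treatment_code == k])
    }, numeric(1)),
    person_years = vapply(codes, function(k) {
      sum(rate$person_years[rate$treatment_code == k])
    }, numeric(1))
  )

  pair_keys <- character(0)
  for (s in studies) {
    pr <- utils::combn(s$treatments, 2)
    pair_keys <- c(pair_keys, paste(pr[1, ], pr[2, ], sep = "-"))
  }
  tab <- table(pair_keys)
  if (length(tab)) {
    sp <- strsplit(names(tab), "-", fixed = TRUE)
    edges <- data.frame(
      treatment1 = as.integer(vapply(sp, `[`, "", 1)),
      treatment2 = as.integer(vapply(sp, `[`, "", 2)),
      n_trials = as.integer(tab)
    )
    edges <- edges[order(edges$treatment1, edges$treatment2), ]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(treatment1 = integer(), treatment2 = integer(),
                        n_trials = integer())
  }
  list(nodes = nodes, edges = edges)
}
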