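#' Generate a random knowledge map with prescribed shape statistics
#'
#' Emulates the stated structure of a large curated regulatory database:
#' directed edges placed uniformly at random without duplicates until exactly
#' `round(n_nodes * mean_degree)` (or `n_edges`) edges exist; each edge is
#' independently positive with probability `positive_fraction` (else
#' negative); magnitudes are drawn uniformly from `weight_range` (default
#' exactly 1, the curation convention that a relationship is +/-1 unless a
#' fractional strength is documented); a fraction of edges is replaced by
#' indeterminate ("I"). Self-loops are permitted. Reproducible from `seed`.
#'
#' Defaults follow the published database shape: mean degree 27566/3589 (~7.68) and positive
#' fraction 0.66. Only the mean degree is emulated — no hub structure.
#'
#' @param n_nodes number of concepts.
#' @param mean_degree edges per node; default `27566/3589`.
#' @param positive_fraction probability an edge is positive; default 0.66.
#' @param indeterminate_fraction fraction of edges replaced by "I"; default 0.
#' @param weight_range interval for edge magnitudes, a sub-interval of (0, 1];
#'   default `c(1, 1)`.
#' @param n_edges explicit edge count, overriding `mean_degree`.
#' @param labels optional label vector; default `N0001 ...`.
#' @param seed integer seed; the generator does not disturb the caller's RNG
#'   state.
#' @return a [knowledge_map].
#' @export
generate_random_map <- function(n_nodes, mean_degree = 27566 / 3589,
                                positive_fraction = 0.66,
                                indeterminate_fraction = 0,
                                weight_range = c(1, 1),
                                n_edges = NULL, labels = NULL, seed = NULL) {
  n_nodes <- as.integer(n_nodes)
  if (n_nodes < 1L) stop_ncm("domain_error", "n_nodes must be >= 1")
  if (n_nodes > 46340L) {
    stop_ncm("domain_error", "n_nodes too large for dense cell sampling")
  }
  if (is.null(n_edges)) n_edges <- round(n_nodes * mean_degree)
  n_edges <- as.integer(n_edges)
  if (n_edges > n_nodes^2) {
    stop_ncm("domain_error", sprintf(
      "%d edges requested but an %d-node map has only %d cells",
      n_edges, n_nodes, n_nodes^2))
  }
  if (positive_fraction < 0 || positive_fraction > 1 ||
      indeterminate_fraction < 0 || indeterminate_fraction > 1) {
    stop_ncm("domain_error", "fractions must lie in [0, 1]")
  }
  if (weight_range[1] <= 0 || weight_range[2] > 1 ||
      weight_range[1] > weight_range[2]) {
    stop_ncm("domain_error", "weight_range must be within (0, 1]")
  }
  if (is.null(labels)) {
    labels <- sprintf("N%0*d", nchar(n_nodes), seq_len(n_nodes))
  }
  with_local_seed(seed, {
    cell <- sample.int(n_nodes^2, n_edges)
    sgn <- ifelse(stats::runif(n_edges) < positive_fraction, 1, -1)
    mag <- if (weight_range[1] == weight_range[2]) {
      rep(weight_range[1], n_edges)
    } else {
      stats::runif(n_edges, weight_range[1], weight_range[2])
    }
    w <- sgn * mag
    if (indeterminate_fraction > 0) {
      w[stats::runif(n_edges) < indeterminate_fraction] <- NA_real_
    }
    knowledge_map(labels, data.frame(
      from = (cell - 1L) %% n_nodes + 1L,
      to = (cell - 1L) %/% n_nodes + 1L,
      weight = w
    ))
  })
}

#' Generate a map with an analytically known attractor
#'
#' Plants one node `P` with a unit self-loop fed by locked driver nodes whose
#' weights sum to `(g - 1)^2 / g`, where `g = loop_gain`. Under Elliott
#' squashing the planted node's update is `x <- f(c + x)` with constant drive
#' `c = (g-1)^2/g`, whose unique non-negative fixed point is exactly
#' `x* = (g - 1) / g` (at the fixed point the raw input is `g - 1` and
#' `f(g - 1) = (g-1)/g`; the local contraction factor is `1/g^2 < 1`).
#' Remaining nodes are fillers with no incoming edges, whose steady value is 0.
#'
#' @param n_nodes total node count (must accommodate planted node + drivers).
#' @param loop_gain effective gain `g >= 1`; `g = 1` plants the zero attractor.
#' @param seed optional seed; shuffles node order only.
#' @return list with `map`, `steady_state` (the analytic attractor, named),
#'   and the `protocol` (drivers locked on) that realizes it.
#' @export
generate_planted_attractor_map <- function(n_nodes, loop_gain, seed = NULL) {
  if (!is.finite(loop_gain) || loop_gain < 1) {
    stop_ncm("domain_error", "loop_gain must be >= 1")
  }
  drive <- (loop_gain - 1)^2 / loop_gain
  n_drivers <- if (drive == 0) 0L else as.integer(ceiling(drive - 1e-12))
  if (n_nodes < 1L + n_drivers) {
    stop_ncm("domain_error", sprintf(
      "gain %g needs %d driver(s) plus the planted node, but n_nodes = %d",
      loop_gain, n_drivers, n_nodes))
  }
  labels <- c("P", if (n_drivers) paste0("D", seq_len(n_drivers)),
              if (n_nodes > 1L + n_drivers) {
                paste0("F", seq_len(n_nodes - 1L - n_drivers))
              })
  steady <- stats::setNames(numeric(n_nodes), labels)
  steady["P"] <- (loop_gain - 1) / loop_gain
  if (n_drivers) steady[paste0("D", seq_len(n_drivers))] <- 1
  with_local_seed(seed, {
    ord <- if (is.null(seed)) seq_len(n_nodes) else sample.int(n_nodes)
    labels <- labels[ord]
    steady <- steady[ord]
    p_idx <- match("P", labels)
    edges <- data.frame(from = p_idx, to = p_idx, weight = 1)
    if (n_drivers) {
      edges <- rbind(edges, data.frame(
        from = match(paste0("D", seq_len(n_drivers)), labels),
        to = p_idx,
        weight = drive / n_drivers
      ))
    }
    list(
      map = knowledge_map(labels, edges),
      steady_state = steady,
      protocol = simulation_protocol(
        locked_on = if (n_drivers) paste0("D", seq_len(n_drivers))
                    else character(0))
    )
  })
}

#' Toy stem-cell reprogramming fixture
#'
#' A hand-written 36-node knowledge map whose wiring is openly fictional: it
#' demonstrates protocol mechanics (transient reprogramming factors igniting a
#' self-sustaining core, a locked-off gene repressing/derepressing a marker
#' panel), not biology. It ships with two protocols and two expected-outcome
#' panels:
#' \describe{
#'   \item{oskm}{OCT3/4, SOX2, KLF4, CMYC transiently turned on (not locked);
#'     the mutually reinforcing core settles positive and drives all 15
#'     pluripotency-panel markers up.}
#'   \item{rett}{the neural conversion recipe — SOX2 on, LET7 off — with
#'     MECP2 locked off; 9 MECP2-repressed genes come up, 2 MECP2-activated
#'     genes go down.}
#' }
#'
#' The same files are shipped as plain text under
#' `system.file("extdata", "toy_stemcell", package = "ncmsim")`.
#'
#' @return list with `map`, `protocols` (list `oskm`, `rett`), and `panels`
#'   (list `pluripotency`, `rett`) as data frames `(label, expected)`.
#' @export
toy_stemcell_fixture <- function() {
  core <- c("OCT3/4", "SOX2", "KLF4", "CMYC")
  pluri_extra <- c("NANOG", "GDF3", "REX1", "FGF4", "ESG1", "DPPA2", "DPPA4",
                   "TERT", "SSEA3", "SSEA4", "TRA-1-81", "ALP", "LIN28")
  pluripotency <- c("OCT3/4", "SOX2", pluri_extra)   # 15 markers
  nsc <- c("PAX6", "NESTIN", "VIMENTIN")
  neuronal <- c("TUBB3", "MAP2", "DCX")
  rett_up <- c("BDNF", "FKBP5", "IGF2", "DLX5", "DLX6", "SGK1", "MPP1",
               "GAMT", "FXYD1")
  rett_down <- c("UBE3A", "GRID1")
  labels <- c(core, pluri_extra, nsc, neuronal, "LET7", "MECP2",
              rett_up, rett_down)

  ed <- function(from, to, weight) data.frame(from = from, to = to,
                                              weight = weight)
  e <- list()
  # self-sustaining reprogramming core: every ordered pair incl. self-loops,
  # all +1 -> symmetric raw input 4x, Elliott fixed point 0.75
  e[[1]] <- expand.grid(from = core, to = core, stringsAsFactors = FALSE)
  e[[1]]$weight <- 1
  # pluripotency markers driven by OCT3/4 and SOX2
  e[[2]] <- ed(rep(c("OCT3/4", "SOX2"), each = length(pluri_extra)),
               rep(pluri_extra, 2L), 1)
  # neural lineage driven by SOX2; early neuronal markers by PAX6
  e[[3]] <- ed("SOX2", nsc, 1)
  e[[4]] <- ed("PAX6", neuronal, 1)
  # LET7 represses LIN28 (flavour); one indeterminate curation entry
  e[[5]] <- ed("LET7", "LIN28", -1)
  e[[6]] <- ed("CMYC", "TERT", NA_real_)
  # MECP2 represses the Rett up-panel and activates the down-panel, so
  # locking MECP2 off (-1) flips the panel the documented way
  e[[7]] <- ed("MECP2", rett_up, -1)
  e[[8]] <- ed("MECP2", rett_down, 1)
  edges <- do.call(rbind, e)
  map <- knowledge_map(labels, data.frame(
    from = match(edges$from, labels),
    to = match(edges$to, labels),
    weight = edges$weight
  ))
  list(
    map = map,
    protocols = list(
      oskm = simulation_protocol(on = core),
      rett = simulation_protocol(on = "SOX2", off = "LET7",
                                 locked_off = "MECP2")
    ),
    panels = list(
      pluripotency = data.frame(label = pluripotency, expected = "up"),
      rett = data.frame(label = c(rett_up, rett_down),
                        expected = rep(c("up", "down"),
                                       c(length(rett_up), length(rett_down))))
    )
  )
}

#' Write the toy fixture as plain-text files
#'
#' Emits `map.csv` (relationship-matrix dialect), `protocol_oskm.dcf`,
#' `protocol_rett.dcf`, `panel_pluripotency.csv` and `panel_rett.csv` into
#' `dir`. Every file carries a comment declaring the wiring synthetic.
#'
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_toy_fixture <- function(dir) {
  fx <- toy_stemcell_fixture()
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  note <- "SYNTHETIC fixture: hand-written, openly fictional wiring; demonstrates protocol mechanics, not biology."
  save_map(fx$map, file.path(dir, "map.csv"), comment = note)
  write_protocol_file(fx$protocols$oskm, file.path(dir, "protocol_oskm.dcf"),
                      note = note)
  write_protocol_file(fx$protocols$rett, file.path(dir, "protocol_rett.dcf"),
                      note = note)
  for (p in names(fx$panels)) {
    path <- file.path(dir, paste0("panel_", p, ".csv"))
    writeLines(c(paste0("# ", note), "label,expected",
                 paste(csv_quote(fx$panels[[p]]$label),
                       fx$panels[[p]]$expected, sep = ",")), path)
  }
  invisible(dir)
}

# evaluate expr with a temporary RNG state when seed is given
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
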