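#' @useDynLib lbbbsim, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats approx median optimize rnorm runif quantile setNames
#' @importFrom utils modifyList read.table write.table head tail
NULL

CONDUCTION_NODES <- c("NSA", "RA", "LA", "NAV", "UH", "RBB", "LBB")

#' Names of the 26 conduction automata
#'
#' The conduction system is modelled as 26 interacting cellular automata:
#' the sinoatrial node (NSA), right and left atria (RA, LA), the
#' atrioventricular node (NAV), the upper bundle of His (UH), the right and
#' left bundle branches (RBB, LBB), 3 right-ventricular segments and the 16
#' AHA left-ventricular segments.
#'
#' @return character vector of length 26.
#' @export
conduction_nodes <- function() {
  c(CONDUCTION_NODES, rv_segments(), aha_segments())
}

default_phase_table <- function(rr = 900) {
  nodes <- conduction_nodes()
  n <- length(nodes)
  cls <- node_class(nodes)
  t_udp <- c(NSA = 1, RA = 2, LA = 2, NAV = 100, UH = 2, RBB = 2, LBB = 2)[nodes]
  t_udp[is.na(t_udp)] <- 2                       # ventricular segments
  t_arp <- ifelse(cls == "atrial", 200, 250)
  t_arp[nodes == "NSA"] <- 150
  t_rrp <- rep(100, n)
  t_sdd <- rep(Inf, n)                           # non-pacemakers wait for a stimulus
  t_sdd[nodes == "NSA"] <- rr - (1 + 150 + 100)  # RR = sum of the four NSA phases
  data.frame(
    id = nodes, t_sdd = t_sdd, t_udp = t_udp, t_arp = t_arp, t_rrp = t_rrp,
    is_pacemaker = nodes == "NSA", class = cls, stringsAsFactors = FALSE
  )
}

node_class <- function(id) {
  ifelse(id == "NSA", "pacemaker",
    ifelse(id %in% c("RA", "LA"), "atrial",
      ifelse(id %in% c("NAV", "UH", "RBB", "LBB"), "conduction", "ventricular")
    )
  )
}

default_link_table <- function(myocardial_delay = 1, lbbb = FALSE) {
  fixed <- data.frame(
    from = c(
      "NSA", "RA", "RA", "NAV", "UH", "UH",
      "RBB", "RBB", "RBB",
      "LBB", "LBB", "LBB", "LBB", "LBB"
    ),
    to = c(
      "RA", "LA", "NAV", "UH", "RBB", "LBB",
      "rv_basal", "rv_median", "rv_apical",
      "basal_anteroseptal", "basal_inferoseptal",
      "mid_anteroseptal", "mid_inferoseptal", "apical_septal"
    ),
    delay = c(5, 8, 5, 2, 2, 2, 10, 13, 16, 4, 4, 6, 6, 8),
    stringsAsFactors = FALSE
  )
  if (lbbb) fixed <- fixed[fixed$from != "LBB", ]
  adj <- segment_adjacency()
  myo <- data.frame(
    from = c(adj$a, adj$b), to = c(adj$b, adj$a),
    delay = myocardial_delay, stringsAsFactors = FALSE
  )
  rbind(fixed, myo)
}

#' Build the cardiac conduction network
#'
#' Constructs and validates the network of cellular automata. Each automaton
#' cycles through four phases -- slow diastolic depolarization (SDD), upstroke
#' depolarization (UDP), absolute refractory period (ARP) and relative
#' refractory period (RRP) -- and stimulates its neighbours when its UDP ends.
#' Only the sinoatrial node self-fires; its SDD is derived from the requested
#' RR interval so that heart rate is a single input.
#'
#' The default topology routes NSA -> RA -> \{LA, NAV\} -> UH -> \{RBB, LBB\},
#' the bundle branches to the ventricular segments, and adds slow
#' cell-to-cell myocardial links between anatomically adjacent wall segments
#' (including trans-septal RV-to-septum contacts). With `lbbb = TRUE` the
#' left bundle branch's outgoing links are removed, so the LV activates via
#' the right bundle and trans-septal myocardial spread, reproducing the
#' septal-to-lateral activation delay of left bundle branch block.
#'
#' @param rr RR interval (ms); the steady-state sinus period.
#' @param lbbb logical; disable the left bundle branch outgoing links.
#' @param myocardial_delay conduction delay (ms) of each cell-to-cell
#'   myocardial link. Larger values widen the QRS in LBBB configurations.
#' @param phases optional data frame overriding rows of the default phase
#'   table (columns `id` plus any of `t_sdd`, `t_udp`, `t_arp`, `t_rrp`).
#' @param links optional data frame (`from`, `to`, `delay`) replacing the
#'   default link table.
#' @param rrp_response `"scaled"`: a stimulus arriving during the RRP
#'   triggers an activation whose UDP is shortened in proportion to the
#'   elapsed RRP fraction; `"normal"`: full UDP.
#' @param event_cap maximum number of processed events before aborting
#'   (guards against runaway re-entry).
#' @return object of class `conduction_network`.
#' @export
#' @examples
#' net <- build_network(rr = 900)
#' length(net$nodes$id) # 26 automata
build_network <- function(rr = 900, lbbb = FALSE, myocardial_delay = 1,
                          phases = NULL, links = NULL,
                          rrp_response = c("scaled", "normal"),
                          event_cap = 100000L) {
  rrp_response <- match.arg(rrp_response)
  if (!is.numeric(rr) || length(rr) != 1 || rr <= 260) {
    stop("rr must be a single duration (ms) exceeding the NSA refractory phases")
  }
  nodes <- default_phase_table(rr)
  if (!is.null(phases)) {
    if (!all(phases$id %in% nodes$id)) {
      bad <- setdiff(phases$id, nodes$id)
      stop("unknown node id in phase overrides: ", paste(bad, collapse = ", "))
    }
    for (col in intersect(c("t_sdd", "t_udp", "t_arp", "t_rrp"), names(phases))) {
      idx <- match(phases$id, nodes$id)
      nodes[[col]][idx] <- phases[[col]]
    }
  }
  if (is.null(links)) {
    links <- default_link_table(myocardial_delay, lbbb = lbbb)
  } else if (lbbb) {
    links <- links[links$from != "LBB", ]
  }

  for (col in c("t_sdd", "t_udp", "t_arp", "t_rrp")) {
    bad <- which(nodes[[col]] < 0 | is.na(nodes[[col]]))
    if (length(bad)) {
      stop(
        "negative or missing duration ", col, " for node ",
        paste(nodes$id[bad], collapse = ", ")
      )
    }
  }
  unknown <- setdiff(unique(c(links$from, links$to)), nodes$id)
  if (length(unknown)) {
    stop("unknown node id in links: ", paste(unknown, collapse = ", "))
  }
  if (any(links$delay < 0)) stop("negative link delay")
  if (any(links$to == "NSA")) stop("NSA must have no incoming links")

  net <- structure(
    list(
      nodes = nodes, links = links, rr = rr, lbbb = lbbb,
      rrp_response = rrp_response, event_cap = as.integer(event_cap)
    ),
    class = "conduction_network"
  )
  reach <- reachable_from(net, "NSA")
  segs <- aha_segments(include_rv = TRUE)
  miss <- setdiff(segs, reach)
  if (length(miss)) {
    stop("ventricular segments unreachable from NSA: ", paste(miss, collapse = ", "))
  }
  net
}

reachable_from <- function(net, start) {
  seen <- start
  frontier <- start
  while (length(frontier)) {
    nxt <- unique(net$links$to[net$links$from %in% frontier])
    frontier <- setdiff(nxt, seen)
    seen <- c(seen, frontier)
  }
  seen
}

#' @export
print.conduction_network <- function(x, ...) {
  cat(
    "<conduction_network> ", nrow(x$nodes), " automata, ",
    nrow(x$links), " links, RR = ", x$rr, " ms",
    if (x$lbbb) ", LBBB (left bundle disabled)" else "", "\n",
    sep = ""
  )
  invisible(x)
}

#' Run the discrete-event conduction simulation
#'
#' Processes the global event queue in deterministic order (priority by time,
#' ties broken by source node order) up to `until_time`. A node in SDD that
#' receives a stimulus enters UDP; a node in its ARP ignores stimuli; a node
#' in its RRP responds according to the network's `rrp_response` policy.
#' When an activation's UDP ends, stimuli are sent to all neighbours with the
#' configured per-link delays.
#'
#' @param network a `conduction_network`.
#' @param until_time simulate activations with onset < `until_time` (ms).
#' @return data frame of activation events: `time` (onset, ms), `node`,
#'   `source` (stimulating node or `NA` for pacemaker self-firing), and
#'   `udp` (UDP duration used for this activation, ms).
#' @export
advance <- function(network, until_time) {
  stopifnot(inherits(network, "conduction_network"))
  if (!is.numeric(until_time) || until_time <= 0) {
    stop("until_time must be a positive time (ms)")
  }
  nodes <- network$nodes
  nid <- nodes$id
  n <- length(nid)
  links_from <- match(network$links$from, nid)
  links_to <- match(network$links$to, nid)
  links_delay <- network$links$delay

  last_onset <- rep(-Inf, n)
  udp_used <- nodes$t_udp

  # event queues as parallel vectors; source index 0 encodes self-firing
  ev_time <- numeric(0)
  ev_target <- integer(0)
  ev_source <- integer(0)

  push <- function(t, target, source) {
    ev_time[length(ev_time) + 1L] <<- t
    ev_target[length(ev_target) + 1L] <<- target
    ev_source[length(ev_source) + 1L] <<- source
  }

  out_time <- numeric(0)
  out_node <- integer(0)
  out_source <- integer(0)
  out_udp <- numeric(0)

  activate <- function(i, t, udp) {
    last_onset[i] <<- t
    udp_used[i] <<- udp
    out_time[length(out_time) + 1L] <<- t
    out_node[length(out_node) + 1L] <<- i
    out_udp[length(out_udp) + 1L] <<- udp
    sel <- which(links_from == i)
    for (k in sel) push(t + udp + links_delay[k], links_to[k], i)
    if (nodes$is_pacemaker[i]) {
      period <- udp + nodes$t_arp[i] + nodes$t_rrp[i] + nodes$t_sdd[i]
      push(t + period, i, 0L)
    }
  }

  # prime pacemakers: first self-firing at t = 0
  for (i in which(nodes$is_pacemaker)) {
    push(0, i, 0L)
    # placeholder source for the initial firing
  }

  processed <- 0L
  while (length(ev_time)) {
    j <- order(ev_time, ev_source)[1L]
    t <- ev_time[j]
    tgt <- ev_target[j]
    src <- ev_source[j]
    ev_time <- ev_time[-j]
    ev_target <- ev_target[-j]
    ev_source <- ev_source[-j]
    if (t >= until_time) next
    processed <- processed + 1L
    if (processed > network$event_cap) {
      stop("event cap exceeded (", network$event_cap, " events): runaway re-entry?")
    }

    if (src == 0L && nodes$is_pacemaker[tgt]) {
      # scheduled self-firing; superseded if the node was restimulated since
      if (is.finite(last_onset[tgt])) {
        period <- udp_used[tgt] + nodes$t_arp[tgt] + nodes$t_rrp[tgt] + nodes$t_sdd[tgt]
        if (t < last_onset[tgt] + period - 1e-9) next
      }
      out_source[length(out_source) + 1L] <- NA_integer_
      activate(tgt, t, nodes$t_udp[tgt])
      next
    }

    elapsed <- t - last_onset[tgt]
    u <- udp_used[tgt]
    arp_end <- u + nodes$t_arp[tgt]
    rrp_end <- arp_end + nodes$t_rrp[tgt]
    if (elapsed < arp_end) next            # UDP or ARP: stimulus ignored
    if (elapsed < rrp_end) {               # RRP
      if (network$rrp_response == "scaled") {
        frac <- (elapsed - arp_end) / nodes$t_rrp[tgt]
        out_source[length(out_source) + 1L] <- src
        activate(tgt, t, nodes$t_udp[tgt] * (0.5 + 0.5 * frac))
      } else {
        out_source[length(out_source) + 1L] <- src
        activate(tgt, t, nodes$t_udp[tgt])
      }
      next
    }
    # SDD (or never activated): normal activation
    out_source[length(out_source) + 1L] <- src
    activate(tgt, t, nodes$t_udp[tgt])
  }

  ord <- order(out_time, out_node)
  data.frame(
    time = out_time[ord],
    node = nid[out_node[ord]],
    source = ifelse(is.na(out_source[ord]), NA_character_, nid[pmax(out_source[ord], 1L)]),
    udp = out_udp[ord],
    stringsAsFactors = FALSE
  )
}

#' Per-node activation onset times for one cycle
#'
#' Cycles are delimited by consecutive sinoatrial (NSA) firings. Returns each
#' node's first activation onset within the requested cycle, relative to the
#' cycle start; nodes never activated in the cycle are `NA`.
#'
#' @param events event data frame from [advance()].
#' @param cycle_index 1-based cycle number.
#' @return named numeric vector (ms relative to cycle start) over all nodes
#'   present in `events`' network.
#' @export
activation_times <- function(events, cycle_index = 1) {
  nsa <- events$time[events$node == "NSA"]
  if (length(nsa) == 0) {
    # degenerate networks (e.g. single node): one cycle starting at the
    # first event
    if (cycle_index != 1) stop("cycle_index beyond simulated horizon")
    t0 <- min(events$time)
    t1 <- Inf
  } else {
    if (cycle_index < 1 || cycle_index > length(nsa)) {
      stop("cycle_index beyond simulated horizon (", length(nsa), " cycles)")
    }
    t0 <- nsa[cycle_index]
    t1 <- if (cycle_index < length(nsa)) nsa[cycle_index + 1] else Inf
  }
  in_cycle <- events[events$time >= t0 & events$time < t1, ]
  nodes <- unique(events$node)
  onset <- setNames(rep(NA_real_, length(nodes)), nodes)
  first <- in_cycle[!duplicated(in_cycle$node), ]
  onset[first$node] <- first$time - t0
  onset
}
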