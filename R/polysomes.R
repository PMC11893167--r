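# Stage 5: putative polysome chains among import-oriented ribosomes.
# A directed link i -> j is drawn when (1) the centers are within the
# neighbor cutoff (30 nm) and (2) the 3' mRNA entry of i is directly
# adjacent to the 5' mRNA exit of j (entry-exit distance <= the adjacency
# cutoff); j is then i's 3'-ward successor on the shared mRNA. Each node
# keeps at most one inbound and one outbound link (smallest adjacency
# distance wins, because mRNA threads single-stranded through a ribosome);
# chains are the maximal simple paths with >= 2 members, ordered 5' -> 3'.

#' Detect putative polysome chains
#'
#' @param particles A [particle_table()] of import-oriented ribosomes (one
#'   tomogram).
#' @param offsets [body_frame_offsets()] giving the mRNA entry/exit sites.
#' @param cfg [run_config()]: `polysome_neighbor` (nm) and
#'   `adjacency_cutoff` (Angstrom).
#' @return A list of class `polysome_chains`: each element holds `members`
#'   (particle row indices ordered 5' to 3'), `end_to_end` (Angstrom,
#'   straight-line 5' exit of the first member to 3' entry of the last) and
#'   `path_length` (Angstrom, intra-ribosome spans plus inter-ribosome mRNA
#'   gaps). Cycles (rare, from symmetric geometry) are broken at their
#'   weakest link and reported via a message.
#' @export
detect_chains <- function(particles, offsets = body_frame_offsets(),
                          cfg = run_config()) {
  n <- nrow(particles)
  ctr <- particle_centers(particles)
  ang <- particle_angles(particles)
  entry <- body_point_to_tomogram(ctr, ang, offsets$mrna_entry)
  exitp <- body_point_to_tomogram(ctr, ang, offsets$mrna_exit)
  if (n < 2)
    return(structure(list(), class = "polysome_chains",
                     entry = entry, exit = exitp))

  neigh <- cfg$polysome_neighbor * 10 # nm -> A
  cand_i <- integer(0); cand_j <- integer(0); cand_d <- numeric(0)
  for (i in seq_len(n)) {
    dc <- rownorms(sweep(ctr, 2, ctr[i, ]))
    for (j in which(dc <= neigh)) {
      if (j == i) next
      da <- vnorm(entry[i, ] - exitp[j, ])
      if (da <= cfg$adjacency_cutoff) {
        cand_i <- c(cand_i, i); cand_j <- c(cand_j, j)
        cand_d <- c(cand_d, da)
      }
    }
  }
  succ <- rep(NA_integer_, n)
  pred <- rep(NA_integer_, n)
  if (length(cand_i)) {
    ord <- order(cand_d, cand_i, cand_j)
    for (k in ord) {
      i <- cand_i[k]; j <- cand_j[k]
      if (is.na(succ[i]) && is.na(pred[j])) {
        succ[i] <- j; pred[j] <- i
        # remember the accepted distance for cycle breaking
        attr(succ, "d") <- c(attr(succ, "d"), stats::setNames(cand_d[k], i))
      }
    }
  }

  # break cycles at the weakest (largest-distance) accepted link
  dmap <- attr(succ, "d")
  attr(succ, "d") <- NULL
  visited <- rep(FALSE, n)
  for (s in seq_len(n)) {
    if (visited[s]) next
    path <- integer(0)
    node <- s
    while (!is.na(node) && !(node %in% path)) {
      path <- c(path, node)
      node <- succ[node]
    }
    visited[path] <- TRUE
    if (!is.na(node)) { # found a cycle
      cyc <- path[seq.int(match(node, path), length(path))]
      d_in_cyc <- dmap[as.character(cyc)]
      weakest <- cyc[which.max(d_in_cyc)]
      message(sprintf("breaking polysome cycle of %d at its weakest link",
                      length(cyc)))
      pred[succ[weakest]] <- NA_integer_
      succ[weakest] <- NA_integer_
    }
  }

  chains <- list()
  for (s in which(is.na(pred) & !is.na(succ))) {
    mem <- s
    node <- succ[s]
    while (!is.na(node)) {
      mem <- c(mem, node)
      node <- succ[node]
    }
    first <- mem[1]; last <- mem[length(mem)]
    span <- vapply(mem, function(i) vnorm(entry[i, ] - exitp[i, ]), 0)
    gaps <- vapply(seq_len(length(mem) - 1), function(t)
      vnorm(entry[mem[t], ] - exitp[mem[t + 1], ]), 0)
    chains[[length(chains) + 1L]] <- list(
      members = mem,
      end_to_end = vnorm(exitp[first, ] - entry[last, ]),
      path_length = sum(span) + sum(gaps)
    )
  }
  structure(chains, class = "polysome_chains",
            tomogram_id = particles$tomogram_id[1],
            entry = entry, exit = exitp)
}

#' @export
print.polysome_chains <- function(x, ...) {
  cat(sprintf("<polysome_chains> %d chain(s)\n", length(x)))
  for (k in seq_along(x))
    cat(sprintf("  #%d: %d members, end-to-end %.0f A, path %.0f A\n", k,
                length(x[[k]]$members), x[[k]]$end_to_end,
                x[[k]]$path_length))
  invisible(x)
}

#' Tabulate detected polysome chains
#'
#' @param chains A `polysome_chains` from [detect_chains()].
#' @return Data frame with `chain_id`, `length`, `end_to_end`,
#'   `path_length`, `tomogram`, plus a `summary` attribute (min / median /
#'   max end-to-end; all `NA` when no chains were found).
#' @export
chain_report <- function(chains) {
  tomo <- attr(chains, "tomogram_id")
  if (is.null(tomo)) tomo <- NA_character_
  if (!length(chains)) {
    df <- data.frame(chain_id = integer(0), length = integer(0),
                     end_to_end = numeric(0), path_length = numeric(0),
                     tomogram = character(0))
    attr(df, "summary") <- c(min = NA_real_, median = NA_real_,
                             max = NA_real_)
    return(df)
  }
  df <- data.frame(
    chain_id = seq_along(chains),
    length = vapply(chains, function(ch) length(ch$members), 0L),
    end_to_end = vapply(chains, `[[`, 0, "end_to_end"),
    path_length = vapply(chains, `[[`, 0, "path_length"),
    tomogram = tomo
  )
  attr(df, "summary") <- c(min = min(df$end_to_end),
                           median = median(df$end_to_end),
                           max = max(df$end_to_end))
  df
}
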