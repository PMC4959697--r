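# Fixture builders. Everything is generated in code at test time; the
# connectome stand-in below is SYNTHETIC: it mimics the shape of a 1024-
# parcel connection study (a single component of 363 edges, five disjoint
# functional modules) but is not the original dataset, so only structural
# quantities (edge counts, capacities, determinism), never published
# q-values, may be asserted against it.

toy_position_study <- function() {
  space <- position_space(1:20, coords = cbind(seq(-38, 38, length.out = 20),
                                               0, 0))
  groups <- position_groups(list(roiA = 1:8, roiB = 11:16))
  annotation <- neuro_annotation(list(VN = c(1:4, 15), AN = c(9, 10, 17),
                                      DMN = c(5, 6, 11, 12)))
  list(space = space, groups = groups, annotation = annotation)
}

# modules sized like a coarse functional parcellation of 1024 parcels;
# planted per-pair edge counts chosen to mirror a Table-2-shaped report
synthetic_connectome <- function(seed = 404L) {
  sizes <- c(VN = 120L, SMN = 180L, DMN = 250L, AN = 60L, VAN = 90L)
  stopifnot(sum(sizes) <= 1024L)
  bounds <- cumsum(c(0L, sizes))
  classes <- lapply(seq_along(sizes),
                    function(i) (bounds[i] + 1L):bounds[i + 1L])
  names(classes) <- names(sizes)
  planted <- list(c("VN", "AN", 72L), c("SMN", "AN", 54L),
                  c("SMN", "VN", 55L), c("VN", "VN", 41L),
                  c("DMN", "DMN", 49L))
  edges <- withr::with_seed(seed, {
    out <- NULL
    for (p in planted) {
      C <- classes[[p[1L]]]
      D <- classes[[p[2L]]]
      if (p[1L] == p[2L]) {
        pool <- t(utils::combn(C, 2L))
      } else {
        pool <- as.matrix(expand.grid(C, D))
      }
      take <- pool[sample.int(nrow(pool), as.integer(p[3L])), , drop = FALSE]
      out <- rbind(out, take)
    }
    # remaining edges among unannotated parcels to reach 363 total
    rest <- 363L - nrow(out)
    free <- (bounds[length(bounds)] + 1L):1024L
    u <- sample(free, rest, replace = TRUE)
    v <- sample(free, rest, replace = TRUE)
    while (any(bad <- u == v | duplicated(paste(pmin(u, v), pmax(u, v))))) {
      u[bad] <- sample(free, sum(bad), replace = TRUE)
      v[bad] <- sample(free, sum(bad), replace = TRUE)
    }
    unname(rbind(out, cbind(u, v)))
  })
  list(space = position_space(1:1024),
       annotation = neuro_annotation(classes),
       groups = connection_groups(list(CC363 = edges)),
       planted = planted)
}

write_toy_position_files <- function(dir) {
  study <- toy_position_study()
  bg <- file.path(dir, "background.txt")
  write.table(cbind(study$space$coords), bg, row.names = FALSE,
              col.names = FALSE)
  gr <- file.path(dir, "groups.txt")
  rows <- do.call(rbind, lapply(seq_along(study$groups$groups), function(i)
    cbind(study$groups$groups[[i]], i)))
  write.table(rows, gr, row.names = FALSE, col.names = FALSE)
  an <- file.path(dir, "annotation.txt")
  arow <- do.call(rbind, lapply(names(study$annotation$classes), function(cl)
    data.frame(id = study$annotation$classes[[cl]], class = cl)))
  write.table(arow, an, row.names = FALSE, col.names = FALSE, quote = FALSE)
  list(background = bg, groups = gr, annotation = an, study = study)
}

write_synthetic_connectome_files <- function(dir, seed = 404L) {
  syn <- synthetic_connectome(seed)
  bg <- file.path(dir, "background.txt")
  write.table(matrix(syn$space$ids, ncol = 1), bg, row.names = FALSE,
              col.names = FALSE)
  cn <- file.path(dir, "connections.txt")
  write.table(cbind(syn$groups$groups[[1L]], 1L), cn, row.names = FALSE,
              col.names = FALSE)
  an <- file.path(dir, "annotation.txt")
  arow <- do.call(rbind, lapply(names(syn$annotation$classes), function(cl)
    data.frame(id = syn$annotation$classes[[cl]], class = cl)))
  write.table(arow, an, row.names = FALSE, col.names = FALSE, quote = FALSE)
  list(background = bg, connections = cn, annotation = an, syn = syn)
}
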