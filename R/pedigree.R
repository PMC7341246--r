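#' Validate and topologically order a pedigree
#'
#' Accepts a tibble with character columns `animal`, `sire`, `dam`
#' (`NA` = unknown). Parents appearing only as parents are added as founder
#' records; records are reordered so parents precede offspring; a cycle
#' (an animal being its own ancestor) is an error naming the cycle.
#'
#' @param ped Pedigree tibble.
#' @return Tibble of class `pedigree_table` with `animal`, `sire`, `dam`
#'   sorted topologically.
#' @export
pedigree_table <- function(ped) {
  ped <- tibble::as_tibble(ped)[, c("animal", "sire", "dam")]
  ped$animal <- as.character(ped$animal)
  ped$sire <- as.character(ped$sire)
  ped$dam <- as.character(ped$dam)
  ped$sire[ped$sire %in% c("0", "")] <- NA_character_
  ped$dam[ped$dam %in% c("0", "")] <- NA_character_
  if (anyDuplicated(ped$animal)) {
    stop("duplicate animal IDs in pedigree", call. = FALSE)
  }
  implicit <- setdiff(stats::na.omit(c(ped$sire, ped$dam)), ped$animal)
  if (length(implicit) > 0L) {
    ped <- dplyr::bind_rows(
      tibble::tibble(animal = implicit, sire = NA_character_,
                     dam = NA_character_),
      ped
    )
  }
  # Kahn topological sort
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$animal)
  s <- idx[ped$sire]
  d <- idx[ped$dam]
  indeg <- as.integer(!is.na(s)) + as.integer(!is.na(d))
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(s[i], d[i])) {
      if (!is.na(p)) children[[p]] <- c(children[[p]], i)
    }
  }
  order_out <- integer(0)
  ready <- which(indeg == 0L)
  while (length(ready) > 0L) {
    i <- ready[1L]
    ready <- ready[-1L]
    order_out <- c(order_out, i)
    for (ch in children[[i]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) ready <- c(ready, ch)
    }
  }
  if (length(order_out) < n) {
    stop("pedigree cycle involving: ",
         paste(ped$animal[setdiff(seq_len(n), order_out)], collapse = ", "),
         call. = FALSE)
  }
  out <- ped[order_out, ]
  class(out) <- c("pedigree_table", class(out))
  out
}

# internal: integer parent indices against the topological order
.ped_index <- function(ped) {
  idx <- stats::setNames(seq_len(nrow(ped)), ped$animal)
  list(
    s = ifelse(is.na(ped$sire), 0L, idx[ped$sire]),
    d = ifelse(is.na(ped$dam), 0L, idx[ped$dam])
  )
}

#' Pedigree inbreeding coefficients
#'
#' Computes each animal's inbreeding coefficient `F` with the
#' Meuwissen-Luo recursion (ancestor-tracing with inbreeding-adjusted
#' Mendelian-sampling variances). Animals with an unknown parent get
#' `F = 0`; unknown parents form a single unrelated base population.
#'
#' @param ped A pedigree tibble (validated through [pedigree_table()]).
#' @return Tibble with `animal` and `f`, in topological order.
#' @export
pedigree_inbreeding <- function(ped) {
  ped <- pedigree_table(ped)
  pi <- .ped_index(ped)
  s <- pi$s
  d <- pi$d
  n <- nrow(ped)
  f <- numeric(n)
  f0 <- function(j) if (j == 0L) -1 else f[j]
  for (i in seq_len(n)) {
    if (s[i] == 0L || d[i] == 0L) {
      f[i] <- 0
      next
    }
    # F_i = a(s,d)/2, accumulated over the ancestor paths of i
    ll <- numeric(n)
    ll[i] <- 1
    anc <- i
    fi <- -1
    while (length(anc) > 0L) {
      j <- max(anc)
      anc <- anc[anc != j]
      if (s[j] > 0L) {
        if (ll[s[j]] == 0 && !(s[j] %in% anc)) anc <- c(anc, s[j])
        ll[s[j]] <- ll[s[j]] + 0.5 * ll[j]
      }
      if (d[j] > 0L) {
        if (ll[d[j]] == 0 && !(d[j] %in% anc)) anc <- c(anc, d[j])
        ll[d[j]] <- ll[d[j]] + 0.5 * ll[j]
      }
      dj <- 0.5 - 0.25 * (f0(s[j]) + f0(d[j]))
      fi <- fi + ll[j]^2 * dj
      ll[j] <- 0
    }
    f[i] <- fi
  }
  tibble::tibble(animal = ped$animal, f = f)
}

#' Inverse numerator relationship matrix
#'
#' Assembles the sparse inverse of the additive (numerator) relationship
#' matrix directly from the pedigree with Henderson's rules, using
#' inbreeding-adjusted Mendelian-sampling variances
#' `d_i = 0.5 - 0.25 (F_s + F_d)` (0.75 - 0.25 F for one known parent, 1
#' for founders).
#'
#' @param ped A pedigree tibble.
#' @return List with `ainv` (sparse symmetric [Matrix::Matrix] with
#'   dimnames = animal IDs, topological order), `f` (the inbreeding tibble)
#'   and `animals`.
#' @export
pedigree_ainverse <- function(ped) {
  ped <- pedigree_table(ped)
  fi <- pedigree_inbreeding(ped)
  pi <- .ped_index(ped)
  s <- pi$s
  d <- pi$d
  f <- fi$f
  n <- nrow(ped)
  ii <- integer(0)
  jj <- integer(0)
  xx <- numeric(0)
  add <- function(a, b, v) {
    ii <<- c(ii, a)
    jj <<- c(jj, b)
    xx <<- c(xx, v)
  }
  for (i in seq_len(n)) {
    fs <- if (s[i] > 0L) f[s[i]] else -1
    fd <- if (d[i] > 0L) f[d[i]] else -1
    di <- 0.5 - 0.25 * (fs + fd)
    al <- 1 / di
    add(i, i, al)
    for (p in c(s[i], d[i])) {
      if (p > 0L) {
        add(i, p, -al / 2)
        add(p, i, -al / 2)
        add(p, p, al / 4)
      }
    }
    if (s[i] > 0L && d[i] > 0L) {
      add(s[i], d[i], al / 4)
      add(d[i], s[i], al / 4)
    }
  }
  ainv <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                               dimnames = list(ped$animal, ped$animal))
  list(ainv = ainv, f = fi, animals = ped$animal)
}
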