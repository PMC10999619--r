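# toy record builders used across test files

toy_records <- function(df) {
  defaults <- data.frame(site = 1L, transect = 1L, stage = "S1",
                         quadrat = "q1", species = "Poa annua",
                         height = 10, cover = 0.2, abundance = 1L,
                         stringsAsFactors = FALSE)
  for (col in names(defaults))
    if (is.null(df[[col]])) df[[col]] <- defaults[[col]]
  validate_survey_records(df[names(defaults)])
}

# n random utilization profiles of length r (rows sum to 1)
random_profiles <- function(n, r) {
  p <- matrix(rgamma(n * r, shape = 0.7), n, r)
  p / rowSums(p)
}

# random symmetric weighted graph on n nodes
random_graph <- function(n, p_edge = 0.5) {
  A <- matrix(0, n, n)
  ut <- upper.tri(A)
  w <- runif(sum(ut))
  w[runif(sum(ut)) >= p_edge] <- 0
  A[ut] <- w
  A + t(A)
}

# two unit-weight triangles, disconnected
two_triangles <- function() {
  W <- matrix(0, 6, 6)
  W[1:3, 1:3] <- 1
  W[4:6, 4:6] <- 1
  diag(W) <- 0
  dimnames(W) <- list(letters[1:6], letters[1:6])
  W
}

# an overlap_matrix built directly from a symmetric value matrix
manual_overlap <- function(values, method = "pianka", stage = "S1") {
  diag(values) <- NA_real_
  sp <- rownames(values) %||% paste0("sp", seq_len(nrow(values)))
  dimnames(values) <- list(sp, sp)
  structure(list(stage = stage, species = sp, method = method,
                 values = values), class = "overlap_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
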