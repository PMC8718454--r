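# Shared fixture builders. Everything is generated in code; no files.

# labeled frame where `det` alone determines the label and the other
# queries are noise: det 0/1 -> N, det 2/3 -> S
depth1_data <- function(n = 40, det = "Q2", others = c("Q4", "Q7"),
                        seed = 42) {
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    code
  }
  withr_seed({
    d <- data.frame(row.names = seq_len(n))
    d[[det]] <- sample(0:3, n, replace = TRUE)
    for (q in others) d[[q]] <- sample(0:3, n, replace = TRUE)
    d$Class <- ifelse(d[[det]] <= 1, "N", "S")
    # make sure all det values and both classes occur
    d[[det]][1:4] <- 0:3
    d$Class <- ifelse(d[[det]] <= 1, "N", "S")
    d
  })
}

depth1_model <- function(...) grow_tree(depth1_data(...))

# tiny raw-response frame with the full 42-query schema
tiny_raw <- function(n = 4, fill = 2L) {
  d <- data.frame(respondent_id = paste0("r", seq_len(n)),
                  stringsAsFactors = FALSE)
  for (q in dass_schema()) d[[q]] <- rep(fill, n)
  d
}

# independent brute-force entropy: explicit loop over class frequencies
oracle_entropy <- function(labels) {
  n <- length(labels)
  h <- 0
  for (cl in unique(labels)) {
    p <- sum(labels == cl) / n
    h <- h - p * log(p, base = 2)
  }
  h
}

# independent brute-force information gain: explicit subset loop
oracle_gain <- function(labels, attr) {
  h <- oracle_entropy(labels)
  for (v in unique(attr)) {
    sub <- labels[attr == v]
    h <- h - length(sub) / length(labels) * oracle_entropy(sub)
  }
  h
}

random_small_table <- function() {
  n <- sample(1:8, 1)
  p <- sample(1:3, 1)
  k <- sample(1:3, 1)
  d <- as.data.frame(matrix(sample(0:3, n * p, replace = TRUE), n, p))
  names(d) <- paste0("Q", seq_len(p))
  d$Class <- sample(c("N", "M", "MD")[seq_len(k)], n, replace = TRUE)
  d
}
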