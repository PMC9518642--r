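# Small internal helpers shared across modules.

## Run `expr` under a fixed RNG seed without disturbing the caller's RNG
## state. `seed = NULL` leaves the RNG alone.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## Population (1/n) variance, the convention used by every dispersion
## statistic in this package.
.pop_var <- function(x) mean((x - mean(x))^2)

## Signed cube root: odd root of possibly negative third moments.
.signed_cbrt <- function(x) sign(x) * abs(x)^(1 / 3)

## Largest-remainder apportionment of `total` units proportional to
## `weights`; ties broken by earlier index.
.largest_remainder <- function(weights, total) {
  exact <- total * weights / sum(weights)
  base <- floor(exact)
  rem <- total - sum(base)
  if (rem > 0) {
    ord <- order(-(exact - base), seq_along(weights))
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}
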