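# Calendar-month arithmetic. Cycles are 4 *calendar* months long, so all
# window computations go through these helpers rather than day counts;
# day-of-month overflow (e.g. Oct 31 + 4 months) clamps to the month end.

days_in_month <- function(month, year) {
  dm <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
  d <- dm[month]
  leap <- (year %% 4 == 0 & year %% 100 != 0) | year %% 400 == 0
  d[month == 2L & leap] <- 29L
  d
}

add_months <- function(dates, n) {
  lt <- as.POSIXlt(dates)
  mon0 <- lt$year * 12L + lt$mon + as.integer(n) # months since 1900-01
  y <- mon0 %/% 12L + 1900L
  m <- mon0 %% 12L + 1L
  d <- pmin(lt$mday, days_in_month(m, y))
  as.Date(sprintf("%04d-%02d-%02d", y, m, d))
}

# Number of whole calendar months from `from` to `to` (to >= from gives >= 0):
# the largest m with add_months(from, m) <= to.
months_between <- function(from, to) {
  lt1 <- as.POSIXlt(from)
  lt2 <- as.POSIXlt(to)
  cand <- (lt2$year - lt1$year) * 12L + (lt2$mon - lt1$mon)
  anchor <- add_months(rep_len(as.Date(from), length(cand)), cand)
  cand - as.integer(rep_len(as.Date(to), length(cand)) < anchor)
}
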