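# Default configuration. Store backends are file-backed serialized stores
# (see store_write/store_read); paths are resolved against the working
# directory unless absolute.
source:
  kind: file
  path: source-store.json
tps_sources: []
archive:
  kind: file
  path: archive-store.json
engine:
  # transfer retries after the first attempt, per record
  max_retries: 7
  # minutes between backup cycles when running in a loop
  cycle_interval_minutes: 10
  state_dir: state
  report_dir: reports
dashboard:
  # a course whose last fraction is at most this many days old is on-treatment
  recency_days: 7
  # study-date window width of the initial roster query, calendar months
  lookback_months: 2
  output: dashboard.csv
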