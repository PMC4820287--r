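# Example site configuration. Every block is optional; omitted values keep
# the package defaults (print them with show_config()).
engine:
  specialty_clinics:
    - vascular surgery
    - cardiology clinic          # sites differ in which clinics manage AAA
  min_age: 40
  max_age: 89
  lookback_years: 5
  reference_date: auto           # or an explicit YYYY-MM-DD anchor
  min_type3_dates: 2
code_sets:
  aaa_repair_px:                 # site-maintained AAA-repair procedure list
    system: CPT
    members: ["34800", "34802", "34803", "34804", "34805",
              "34830", "34831", "34832",
              "35081", "35082", "35091", "35092", "35102", "35103"]
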