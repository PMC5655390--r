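# Regulatory particulate-matter thresholds (ug/m3) used by the exceedance
# summaries. DOE: Iran Department of Environment; EPA: US Environmental
# Protection Agency.
doe_annual_pm25:
  pollutant: pm25
  threshold: 10
  averaging: annual
  agency: DOE
doe_24h_pm25:
  pollutant: pm25
  threshold: 35
  averaging: 24h
  agency: DOE
epa_24h_pm25:
  pollutant: pm25
  threshold: 35
  averaging: 24h
  agency: EPA
doe_annual_pm10:
  pollutant: pm10
  threshold: 20
  averaging: annual
  agency: DOE
doe_24h_pm10:
  pollutant: pm10
  threshold: 154
  averaging: 24h
  agency: DOE
epa_24h_pm10:
  pollutant: pm10
  threshold: 150
  averaging: 24h
  agency: EPA
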