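{
  "type": "FeatureCollection",
  "description": "Approximate Adriatic sub-region polygons, in priority order. WACC is a ~30 km coastal band along the Italian coast from the Po Delta to the Strait of Otranto; the northern boundary of NA (a bathymetric definition in the literature) is approximated by a fixed-latitude chord at 43.2N, and the MA/SA boundary by a chord at 41.9N off the Gargano Peninsula. Edit freely; feature order sets the assignment priority.",
  "features": [
    {
      "type": "Feature",
      "properties": {"name": "WACC"},
      "geometry": {
        "type": "Polygon",
        "coordinates": [[
          [12.45, 44.95], [12.30, 44.20], [13.55, 43.60], [14.05, 42.90],
          [14.90, 42.35], [15.90, 41.95], [16.20, 41.90], [17.10, 41.05],
          [17.95, 40.65], [18.50, 40.05],
          [18.78, 40.23], [18.23, 40.83], [17.38, 41.23], [16.48, 42.08],
          [16.18, 42.13], [15.18, 42.53], [14.33, 43.08], [13.83, 43.78],
          [12.58, 44.38], [12.73, 45.13],
          [12.45, 44.95]
        ]]
      }
    },
    {
      "type": "Feature",
      "properties": {"name": "NA"},
      "geometry": {
        "type": "Polygon",
        "coordinates": [[
          [12.20, 43.20], [16.00, 43.20], [16.00, 45.90], [12.20, 45.90],
          [12.20, 43.20]
        ]]
      }
    },
    {
      "type": "Feature",
      "properties": {"name": "MA"},
      "geometry": {
        "type": "Polygon",
        "coordinates": [[
          [12.80, 41.90], [18.20, 41.90], [18.20, 43.20], [12.80, 43.20],
          [12.80, 41.90]
        ]]
      }
    },
    {
      "type": "Feature",
      "properties": {"name": "SA"},
      "geometry": {
        "type": "Polygon",
        "coordinates": [[
          [14.80, 39.90], [20.00, 39.90], [20.00, 41.90], [14.80, 41.90],
          [14.80, 39.90]
        ]]
      }
    }
  ]
}
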