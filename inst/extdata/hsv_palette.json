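[
  {"name": "black",  "hue": [[0, 180]],            "s": [0, 255], "v": [0, 46]},
  {"name": "gray",   "hue": [[0, 180]],            "s": [0, 43],  "v": [46, 220]},
  {"name": "white",  "hue": [[0, 180]],            "s": [0, 30],  "v": [221, 255]},
  {"name": "red",    "hue": [[0, 10], [156, 180]], "s": [43, 255], "v": [46, 255]},
  {"name": "orange", "hue": [[11, 25]],            "s": [43, 255], "v": [46, 255]},
  {"name": "yellow", "hue": [[26, 34]],            "s": [43, 255], "v": [46, 255]},
  {"name": "green",  "hue": [[35, 77]],            "s": [43, 255], "v": [46, 255]},
  {"name": "cyan",   "hue": [[78, 99]],            "s": [43, 255], "v": [46, 255]},
  {"name": "blue",   "hue": [[100, 124]],          "s": [43, 255], "v": [46, 255]},
  {"name": "purple", "hue": [[125, 155]],          "s": [43, 255], "v": [46, 255]}
]
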