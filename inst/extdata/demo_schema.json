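{
  "version": "demo-1",
  "min_class_frequency": 20,
  "entity_types": [
    {
      "name": "LesionAnchor",
      "role": "anchor",
      "definition": ""
    },
    {
      "name": "CalcificationAnchor",
      "role": "anchor",
      "definition": ""
    },
    {
      "name": "NippleDistanceAnchor",
      "role": "anchor",
      "definition": ""
    },
    {
      "name": "DensityAnchor",
      "role": "anchor",
      "definition": ""
    },
    {
      "name": "LymphNodeAnchor",
      "role": "anchor",
      "definition": ""
    },
    {
      "name": "BiradsAnchor",
      "role": "anchor",
      "definition": ""
    },
    {
      "name": "RecommendationAnchor",
      "role": "anchor",
      "definition": ""
    },
    {
      "name": "SkinAnchor",
      "role": "anchor",
      "definition": ""
    },
    {
      "name": "AsymmetryAnchor",
      "role": "anchor",
      "definition": ""
    },
    {
      "name": "ForeignMaterialAnchor",
      "role": "anchor",
      "definition": ""
    },
    {
      "name": "MamillaAnchor",
      "role": "anchor",
      "definition": ""
    },
    {
      "name": "PriorExamAnchor",
      "role": "anchor",
      "definition": ""
    },
    {
      "name": "MalignancyAnchor",
      "role": "anchor",
      "definition": ""
    },
    {
      "name": "DistortionAnchor",
      "role": "anchor",
      "definition": ""
    },
    {
      "name": "Negation",
      "role": "modifier",
      "definition": ""
    },
    {
      "name": "Side",
      "role": "modifier",
      "definition": ""
    },
    {
      "name": "Quadrant",
      "role": "modifier",
      "definition": ""
    },
    {
      "name": "Shape",
      "role": "modifier",
      "definition": ""
    },
    {
      "name": "Size",
      "role": "modifier",
      "definition": ""
    },
    {
      "name": "ClockPosition",
      "role": "modifier",
      "definition": ""
    },
    {
      "name": "CalcType",
      "role": "modifier",
      "definition": ""
    },
    {
      "name": "Measure",
      "role": "modifier",
      "definition": ""
    },
    {
      "name": "DensityClass",
      "role": "modifier",
      "definition": ""
    },
    {
      "name": "Suspicion",
      "role": "modifier",
      "definition": ""
    },
    {
      "name": "BiradsValue",
      "role": "modifier",
      "definition": ""
    },
    {
      "name": "Interval",
      "role": "modifier",
      "definition": ""
    },
    {
      "name": "Procedure",
      "role": "modifier",
      "definition": ""
    },
    {
      "name": "Finding",
      "role": "modifier",
      "definition": ""
    },
    {
      "name": "MaterialType",
      "role": "modifier",
      "definition": ""
    },
    {
      "name": "PriorDate",
      "role": "modifier",
      "definition": ""
    }
  ],
  "fact_types": [
    {
      "name": "Lesion",
      "anchor": "LesionAnchor",
      "modifier_slots": [
        "Negation",
        "Side",
        "Quadrant",
        "Shape",
        "Size",
        "ClockPosition"
      ],
      "definition": ""
    },
    {
      "name": "Calcification",
      "anchor": "CalcificationAnchor",
      "modifier_slots": [
        "Negation",
        "Side",
        "Quadrant",
        "CalcType"
      ],
      "definition": ""
    },
    {
      "name": "NippleDistance",
      "anchor": "NippleDistanceAnchor",
      "modifier_slots": [
        "Measure"
      ],
      "definition": ""
    },
    {
      "name": "Density",
      "anchor": "DensityAnchor",
      "modifier_slots": [
        "DensityClass",
        "Side"
      ],
      "definition": ""
    },
    {
      "name": "LymphNodes",
      "anchor": "LymphNodeAnchor",
      "modifier_slots": [
        "Negation",
        "Side",
        "Suspicion"
      ],
      "definition": ""
    },
    {
      "name": "BiradsStatement",
      "anchor": "BiradsAnchor",
      "modifier_slots": [
        "BiradsValue",
        "Side"
      ],
      "definition": ""
    },
    {
      "name": "Recommendation",
      "anchor": "RecommendationAnchor",
      "modifier_slots": [
        "Interval",
        "Procedure"
      ],
      "definition": ""
    },
    {
      "name": "SkinFinding",
      "anchor": "SkinAnchor",
      "modifier_slots": [
        "Finding",
        "Side"
      ],
      "definition": ""
    },
    {
      "name": "Asymmetry",
      "anchor": "AsymmetryAnchor",
      "modifier_slots": [
        "Negation",
        "Side"
      ],
      "definition": ""
    },
    {
      "name": "ForeignMaterial",
      "anchor": "ForeignMaterialAnchor",
      "modifier_slots": [
        "Negation",
        "Side",
        "MaterialType"
      ],
      "definition": ""
    },
    {
      "name": "MamillaRegion",
      "anchor": "MamillaAnchor",
      "modifier_slots": [
        "Finding",
        "Side"
      ],
      "definition": ""
    },
    {
      "name": "PriorExams",
      "anchor": "PriorExamAnchor",
      "modifier_slots": [
        "Negation",
        "PriorDate"
      ],
      "definition": ""
    },
    {
      "name": "AdditionalResult",
      "anchor": "MalignancyAnchor",
      "modifier_slots": [
        "Negation"
      ],
      "definition": ""
    },
    {
      "name": "ArchitecturalDistortion",
      "anchor": "DistortionAnchor",
      "modifier_slots": [
        "Negation",
        "Quadrant",
        "Side"
      ],
      "definition": ""
    }
  ]
}
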