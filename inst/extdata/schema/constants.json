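{
  "valueSets": {
    "refsem.Severity": ["severe", "moderate", "slight", "unmarked"],
    "refsem.Course": ["changed", "increased", "decreased", "improved", "worsened", "resolved", "unmarked"],
    "refsem.BodySide": ["left", "right", "bilateral"],
    "refsem.BodyLaterality": ["medial", "lateral", "distal", "proximal", "superior", "inferior", "unmarked"]
  },
  "patterns": {
    "refsem.UMLSConcept": {
      "cui": "^C[0-9]{7}$",
      "tui": "^T[0-9]{3}$"
    }
  },
  "featureDefaults": {
    "polarity": 1,
    "uncertainty": 0,
    "conditional": false,
    "generic": false,
    "subject": "patient"
  },
  "coreCems": [
    "refsem.AnatomicalSite",
    "refsem.DiseaseDisorder",
    "refsem.Lab",
    "refsem.Medication",
    "refsem.Procedure",
    "refsem.SignSymptom"
  ],
  "typeIds": [
    {"code": 0, "group": "unknown", "elementType": null},
    {"code": 1, "group": "medication", "elementType": "refsem.Medication"},
    {"code": 2, "group": "disease/disorder", "elementType": "refsem.DiseaseDisorder"},
    {"code": 3, "group": "sign/symptom", "elementType": "refsem.SignSymptom"},
    {"code": 4, "group": "lab", "elementType": "refsem.Lab"},
    {"code": 5, "group": "procedure", "elementType": "refsem.Procedure"},
    {"code": 6, "group": "anatomical site", "elementType": "refsem.AnatomicalSite"}
  ],
  "temporalCategories": ["startTime", "TIMEX-of"],
  "degreeCategories": ["degreeOf"],
  "liftMap": {
    "degreeOf": "relation.DegreeOf",
    "affects": "relation.Affects",
    "locationOf": "relation.LocationOf",
    "resultOf": "relation.ResultOf",
    "manifestationOf": "relation.ManifestationOf"
  },
  "cemModels": {
    "refsem.AnatomicalSite": "AnatomicalSiteAssert.xml",
    "refsem.DiseaseDisorder": "DiseaseDisorderAssert.xml",
    "refsem.Lab": "LabAssert.xml",
    "refsem.Medication": "MedicationAssert.xml",
    "refsem.Procedure": "ProcedureAssert.xml",
    "refsem.SignSymptom": "SignSymptomAssert.xml"
  },
  "cemModelTypes": {
    "CoughAssert": "refsem.SignSymptom",
    "AnatomicalSiteAssert": "refsem.AnatomicalSite",
    "DiseaseDisorderAssert": "refsem.DiseaseDisorder",
    "LabAssert": "refsem.Lab",
    "MedicationAssert": "refsem.Medication",
    "ProcedureAssert": "refsem.Procedure",
    "SignSymptomAssert": "refsem.SignSymptom"
  }
}
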