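{"text":"Chief complaint: severe cough and fever. Cough started 2 days ago, no expectoration.","metadata":{"documentDate":"2006-09-03"},"annotations":[{"id":1,"type":"textspan.Sentence","begin":0,"end":40,"features":{"sentenceNumber":0}},{"id":2,"type":"textspan.Sentence","begin":41,"end":84,"features":{"sentenceNumber":1}},{"id":3,"type":"refsem.UMLSConcept","features":{"code":"C0010200","codingScheme":"UMLS","cui":"C0010200","tui":"T184"}},{"id":4,"type":"textsem.EventMention","begin":24,"end":29,"features":{"conditional":false,"generic":false,"ontologyConceptArr":[{"$ref":3}],"polarity":1,"subject":"patient","typeID":3,"uncertainty":0}},{"id":5,"type":"refsem.UMLSConcept","features":{"code":"C0015967","codingScheme":"UMLS","cui":"C0015967","tui":"T184"}},{"id":6,"type":"textsem.EventMention","begin":34,"end":39,"features":{"conditional":false,"generic":false,"ontologyConceptArr":[{"$ref":5}],"polarity":1,"subject":"patient","typeID":3,"uncertainty":0}},{"id":7,"type":"refsem.UMLSConcept","features":{"code":"C0010200","codingScheme":"UMLS","cui":"C0010200","tui":"T184"}},{"id":8,"type":"textsem.EventMention","begin":41,"end":46,"features":{"conditional":false,"generic":false,"ontologyConceptArr":[{"$ref":7}],"polarity":1,"subject":"patient","typeID":3,"uncertainty":0}},{"id":9,"type":"refsem.UMLSConcept","features":{"code":"C0034642","codingScheme":"UMLS","cui":"C0034642","tui":"T184"}},{"id":10,"type":"textsem.EventMention","begin":70,"end":83,"features":{"conditional":false,"generic":false,"ontologyConceptArr":[{"$ref":9}],"polarity":-1,"subject":"patient","typeID":3,"uncertainty":0}},{"id":11,"type":"refsem.Severity","features":{"value":"severe"}},{"id":12,"type":"textsem.Modifier","begin":17,"end":23,"features":{"conditional":false,"generic":false,"normalized":{"$ref":11},"polarity":1,"subject":"patient","uncertainty":0}},{"id":13,"type":"textsem.TimeMention","begin":55,"end":65,"features":{"conditional":false,"generic":false,"polarity":1,"subject":"patient","uncertainty":0}},{"id":14,"type":"relation.RelationArgument","features":{"argument":{"$ref":4}}},{"id":15,"type":"relation.RelationArgument","features":{"argument":{"$ref":8}}},{"id":16,"type":"relation.CoreferenceRelation","features":{"arg1":{"$ref":14},"arg2":{"$ref":15},"conditional":false,"polarity":1,"uncertainty":0}},{"id":17,"type":"relation.RelationArgument","features":{"argument":{"$ref":8}}},{"id":18,"type":"relation.RelationArgument","features":{"argument":{"$ref":13}}},{"id":19,"type":"relation.BinaryTextRelation","features":{"arg1":{"$ref":17},"arg2":{"$ref":18},"category":"startTime","conditional":false,"polarity":1,"uncertainty":0}},{"id":20,"type":"relation.RelationArgument","features":{"argument":{"$ref":12}}},{"id":21,"type":"relation.RelationArgument","features":{"argument":{"$ref":4}}},{"id":22,"type":"relation.BinaryTextRelation","features":{"arg1":{"$ref":20},"arg2":{"$ref":21},"category":"degreeOf","conditional":false,"polarity":1,"uncertainty":0}},{"id":23,"type":"relation.RelationArgument","features":{"argument":{"$ref":8}}},{"id":24,"type":"relation.RelationArgument","features":{"argument":{"$ref":10}}},{"id":25,"type":"relation.UMLSRelation","features":{"arg1":{"$ref":23},"arg2":{"$ref":24},"category":"manifestationOf","conditional":false,"polarity":-1,"uncertainty":0}}]}
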