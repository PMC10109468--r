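externalIdentifier,transcriberID,dateTranscribed,isTheImageInFocus,areThereAnyMicrofossilsInThisImage,howManyMicrofossilsArePresent,whereIsTheMicrofossil,whatTypeOfMicrofossilIsPresent
m1_c000_r000,cs-011,2021-03-16 09:12:01,In focus,Without a microfossil,,,
m1_c000_r000,cs-007,2021-03-16 10:05:44,In focus,Without a microfossil,,,
m1_c000_r000,cs-023,2021-03-16 11:30:12,In focus,Without a microfossil,,,
m1_c001_r000,cs-002,2021-03-16 09:14:55,In focus,Without a microfossil,,,
m1_c001_r000,cs-019,2021-03-16 09:58:31,In focus,With a microfossil,1,Middle,Pollen or spore
m1_c001_r000,cs-011,2021-03-16 12:21:09,In focus,Without a microfossil,,,
m1_c001_r000,cs-030,2021-03-16 14:47:26,In focus,Without a microfossil,,,
m1_c002_r000,cs-007,2021-03-16 09:20:18,In focus,With a microfossil,1,Middle,Nothofagidites
m1_c002_r000,cs-023,2021-03-16 10:41:03,In focus,With a microfossil,1,Middle,Nothofagidites
m1_c002_r000,cs-002,2021-03-16 13:02:40,In focus,With a microfossil,1,Middle,Nothofagidites
m1_c003_r000,cs-019,2021-03-16 09:25:57,In focus,With a microfossil,2,Middle and edge,Fern spore
m1_c003_r000,cs-030,2021-03-16 10:13:22,In focus,With a microfossil,1,Edge,Fern spore
m1_c003_r000,cs-011,2021-03-16 11:55:48,Out of focus,Without a microfossil,,,
m1_c003_r000,cs-023,2021-03-16 15:09:34,In focus,With a microfossil,1,Middle,Unknown
m1_c004_r000,cs-030,2021-03-16 16:20:02,In focus,Without a microfossil,,,
m1_c004_r000,cs-002,2021-03-16 09:31:16,In focus,Without a microfossil,,,
m1_c004_r000,cs-007,2021-03-16 12:44:59,In focus,Without a microfossil,,,
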